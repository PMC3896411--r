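#' Select backbone heavy atoms
#'
#' Backbone heavy atoms are N, CA, C and O of protein residues; this is the
#' selection used for RMSD/RMSF fitting.
#'
#' @param structure a `pt_structure`
#' @return integer atom indices
#' @export
select_backbone <- function(structure) {
  a <- structure$atoms
  which(a$resname %in% .protein_resnames &
          a$name %in% c("N", "CA", "C", "O"))
}

.as_xyz <- function(x) {
  if (inherits(x, "pt_structure")) coords(x) else as.matrix(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation/translation minimising the RMSD between the selected
#' atoms of `mobile` and `reference`. The transform maps mobile
#' coordinates (row vectors) as `x %*% t(rotation) + translation`.
#'
#' @param mobile,reference N x 3 coordinate matrices or `pt_structure`s
#' @param selection integer atom indices used for the fit (default: all)
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd` (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  M <- .as_xyz(mobile); R <- .as_xyz(reference)
  if (is.null(selection)) selection <- seq_len(nrow(M))
  if (length(selection) != length(intersect(selection, seq_len(nrow(R)))) ||
      nrow(M) < max(selection))
    stop("selection out of range or selections differ in length")
  m <- M[selection, , drop = FALSE]
  r <- R[selection, , drop = FALSE]
  if (nrow(m) < 3L) stop("degenerate selection: fewer than 3 atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (svd(rc)$d[2] < 1e-8 * max(1, svd(rc)$d[1]))
    stop("degenerate selection: reference atoms are collinear")
  H <- crossprod(mc, rc)            # sum m_i r_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fit <- sweep(mc %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fit - r)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz N x 3 matrix
#' @param transform list with `rotation` and `translation`
#' @return transformed N x 3 matrix
#' @export
apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Pairwise RMSD matrix over a set of structures
#'
#' @param structures list of `pt_structure`s (or coordinate matrices) with
#'   a common atom ordering
#' @param selection atom indices used for fitting (default: all)
#' @return symmetric n x n matrix of least-squares RMSDs (Angstrom), zero
#'   diagonal; n(n-1)/2 unique pairs.
#' @export
pairwise_rmsd_matrix <- function(structures, selection = NULL) {
  n <- length(structures)
  if (n < 2L) stop("need at least 2 structures")
  xyz <- lapply(structures, .as_xyz)
  sizes <- vapply(xyz, nrow, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("selection mismatch: structures have differing atom counts")
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <-
      superpose(xyz[[i]], xyz[[j]], selection)$rmsd
  }
  lbl <- names(structures) %||% as.character(seq_len(n))
  dimnames(out) <- list(lbl, lbl)
  out
}

#' Iteratively fitted average structure of a trajectory
#'
#' Alternates fitting every frame to the current mean (on `selection`) and
#' recomputing the all-atom mean, until the mean moves less than `tol` on
#' average.
#'
#' @param trajectory a `pt_trajectory`
#' @param selection atom indices used for fitting (default: backbone heavy
#'   atoms, falling back to all atoms)
#' @param tol convergence threshold on the mean per-atom shift (Angstrom)
#' @param max_iter iteration cap
#' @return a `pt_structure` holding the converged mean coordinates.
#' @export
average_structure <- function(trajectory, selection = NULL, tol = 1e-6,
                              max_iter = 100L) {
  nf <- n_frames(trajectory)
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(selection)) {
    selection <- select_backbone(trajectory$topology)
    if (length(selection) < 3L) selection <- seq_len(dim(trajectory$frames)[1])
  }
  mean_xyz <- trajectory$frames[, , 1]
  for (it in seq_len(max_iter)) {
    acc <- 0
    for (f in seq_len(nf)) {
      tr <- superpose(trajectory$frames[, , f], mean_xyz, selection)
      acc <- acc + apply_transform(trajectory$frames[, , f], tr)
    }
    new_mean <- acc / nf
    shift <- mean(sqrt(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) return(set_coords(trajectory$topology, mean_xyz))
  }
  stop("convergence error: average structure did not converge in ",
       max_iter, " iterations")
}

#' Root mean-square fluctuation about the average structure
#'
#' Each frame is best-fitted to the iteratively converged average structure
#' on `selection`; the fluctuation is then the RMS deviation from the
#' average, pooled per residue (or reported per atom).
#'
#' @param trajectory a `pt_trajectory`
#' @param selection atom indices included in both the fit and the
#'   fluctuation statistics (default: backbone heavy atoms)
#' @param per_atom if TRUE, return per-atom RMSF over `selection` instead
#'   of per-residue values
#' @return named numeric vector of RMSFs (Angstrom), by residue id or atom
#'   index.
#' @export
rmsf <- function(trajectory, selection = NULL, per_atom = FALSE) {
  if (is.null(selection)) selection <- select_backbone(trajectory$topology)
  if (!length(selection)) stop("empty selection")
  avg <- coords(average_structure(trajectory, selection))
  nf <- n_frames(trajectory)
  ss <- matrix(0, length(selection), 1)
  for (f in seq_len(nf)) {
    tr <- superpose(trajectory$frames[, , f], avg, selection)
    fit <- apply_transform(trajectory$frames[, , f], tr)
    ss <- ss + rowSums((fit[selection, , drop = FALSE] -
                          avg[selection, , drop = FALSE])^2)
  }
  msd <- as.vector(ss) / nf
  if (per_atom) return(setNames(sqrt(msd), selection))
  resid <- trajectory$topology$atoms$resid[selection]
  agg <- tapply(msd, resid, mean)
  setNames(sqrt(as.vector(agg)), names(agg))
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention; result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 position vectors
#' @return angle in degrees
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Propeller angle through four subdomain centroids
#'
#' The inter-domain twist of the actin monomer, measured as the torsion
#' angle of the centroids of the four subdomains taken in `order`.
#'
#' @param structure a `pt_structure`
#' @param subdomains named integer vector from [subdomain_map()]
#' @param order 4-tuple of subdomain ids defining the torsion; the default
#'   (2, 1, 3, 4) runs down one lobe pair and up the other
#' @param selection atom indices eligible for the centroids (default: all
#'   protein atoms)
#' @return angle in degrees in (-180, 180].
#' @export
propeller_angle <- function(structure, subdomains, order = c(2, 1, 3, 4),
                            selection = NULL) {
  a <- structure$atoms
  if (is.null(selection))
    selection <- which(a$resname %in% .protein_resnames)
  xyz <- coords(structure)
  cent <- lapply(order, function(k) {
    res_k <- as.integer(names(subdomains)[subdomains == k])
    idx <- selection[a$resid[selection] %in% res_k]
    if (!length(idx)) stop("empty subdomain: ", k)
    colMeans(xyz[idx, , drop = FALSE])
  })
  torsion_angle(cent[[1]], cent[[2]], cent[[3]], cent[[4]])
}

# side-chain dihedral definitions (atom quadruples per chi)
.chi_defs <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  CYS = list(c("N", "CA", "CB", "SG"))
)

#' Number of rotatable side-chain dihedrals of a residue type
#' @param residue_type 3-letter amino-acid code
#' @return integer count (0 for Gly/Ala)
#' @export
n_chi <- function(residue_type) {
  residue_type <- toupper(residue_type)
  if (residue_type %in% c("GLY", "ALA")) return(0L)
  defs <- .chi_defs[[residue_type]]
  if (is.null(defs)) stop("unknown residue type: ", residue_type)
  length(defs)
}

#' Enumerate canonical side-chain rotamers
#'
#' The Cartesian product of the canonical chi states over all rotatable
#' side-chain dihedrals; with the default gauche-/gauche+/trans states a
#' lysine (4 chi) yields 81 rotamers.
#'
#' @param residue_type 3-letter amino-acid code
#' @param states canonical chi values in degrees
#' @return matrix with one row per rotamer and one column per chi, in
#'   lexicographic order of the chi vector (chi1 most significant).
#'   Glycine/alanine give a 0-row matrix with a warning.
#' @export
enumerate_rotamers <- function(residue_type, states = c(-60, 60, 180)) {
  k <- n_chi(residue_type)
  if (k == 0L) {
    warning(residue_type, " has no rotatable side-chain dihedrals")
    return(matrix(numeric(0), 0, 0))
  }
  g <- expand.grid(rep(list(states), k))[, k:1, drop = FALSE]
  g <- as.matrix(g[do.call(order, as.data.frame(g)), , drop = FALSE])
  dimnames(g) <- list(NULL, paste0("chi", seq_len(k)))
  g
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame construction: the new atom D sits at
#' distance `bond` from C, with angle B-C-D equal to `angle` and torsion
#' A-B-C-D equal to `torsion`.
#'
#' @param a,b,c reference positions (length-3)
#' @param bond Angstrom
#' @param angle,torsion degrees
#' @return length-3 position of the new atom
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d
}

#' Build side-chain heavy atoms for a rotamer on a backbone stub
#'
#' Places CB from the backbone (N, CA, C) with ideal internal coordinates,
#' then grows the side chain one atom per chi using the requested dihedral
#' values. Covers the chain-type residues whose chi definitions are linear
#' (Lys, Arg, Met, Glu/Gln, Ser, Thr, Val, Cys, Asp/Asn, Ile, Leu).
#'
#' @param backbone named list or 3 x 3 matrix with rows/elements `N`, `CA`,
#'   `C` (positions, Angstrom)
#' @param residue_type 3-letter code
#' @param chi numeric vector of dihedrals (degrees), one per rotatable chi
#' @return named matrix of side-chain atom positions (starting at CB).
#' @export
build_sidechain <- function(backbone, residue_type, chi) {
  residue_type <- toupper(residue_type)
  defs <- .chi_defs[[residue_type]]
  if (is.null(defs)) stop("unknown residue type: ", residue_type)
  if (length(chi) != length(defs))
    stop("expected ", length(defs), " chi values")
  pos <- list(N = as.numeric(backbone[["N"]] %||% backbone["N", ]),
              CA = as.numeric(backbone[["CA"]] %||% backbone["CA", ]),
              C = as.numeric(backbone[["C"]] %||% backbone["C", ]))
  # CB: tetrahedral branch off CA
  pos$CB <- as.vector(place_atom(pos$C, pos$N, pos$CA,
                                 1.53, 110.4, -122.5))
  for (k in seq_along(defs)) {
    q <- defs[[k]]
    new <- q[4]
    elem <- substr(new, 1, 1)
    bond <- if (elem == "S") 1.81 else if (elem == "O") 1.42 else 1.52
    pos[[new]] <- as.vector(place_atom(pos[[q[1]]], pos[[q[2]]],
                                       pos[[q[3]]], bond, 112, chi[k]))
  }
  out <- do.call(rbind, pos[-(1:3)])
  rownames(out) <- names(pos)[-(1:3)]
  out
}

#' Select the rotamer whose probe atom lies farthest from an anchor
#'
#' Used for modelling a substituted side chain away from a bound cation:
#' among candidate rotamer-built side chains, picks the state maximising
#' the probe-atom-to-anchor distance. Ties are broken by lexicographic chi
#' order.
#'
#' @param states list, one entry per rotamer, each with `chi` (numeric
#'   vector) and `coords` (named position matrix containing `probe_atom`)
#' @param probe_atom atom name to measure from (e.g. `"NZ"`)
#' @param anchor length-3 anchor position (e.g. the cation)
#' @return the winning state (list with `chi`, `coords`, `distance`).
#' @export
select_rotamer_max_distance <- function(states, probe_atom, anchor) {
  if (!length(states)) stop("no rotamer states supplied")
  d <- vapply(states, function(s) {
    p <- s$coords[probe_atom, ]
    sqrt(sum((p - anchor)^2))
  }, numeric(1))
  if (all(d < 1)) warning("all probe positions clash with the anchor (< 1 A)")
  best <- which(d >= max(d) - 1e-9)
  if (length(best) > 1L) {
    chis <- do.call(rbind, lapply(states[best], `[[`, "chi"))
    best <- best[do.call(order, as.data.frame(chis))[1]]
  } else best <- best[1]
  out <- states[[best]]
  out$distance <- d[best]
  out
}

.residue_chi_series <- function(trajectory, residue_id, chi_index) {
  a <- trajectory$topology$atoms
  ridx <- which(a$resid == residue_id & a$resname %in% .protein_resnames)
  if (!length(ridx)) stop("residue ", residue_id, " not found")
  rn <- a$resname[ridx[1]]
  defs <- .chi_defs[[rn]]
  if (is.null(defs) || chi_index > length(defs))
    stop("residue ", residue_id, " (", rn, ") has no chi", chi_index)
  q <- defs[[chi_index]]
  qi <- vapply(q, function(nm) {
    j <- ridx[a$name[ridx] == nm]
    if (!length(j)) stop("missing side-chain atom ", nm, " in residue ",
                         residue_id)
    j[1]
  }, integer(1))
  vapply(seq_len(n_frames(trajectory)), function(f)
    torsion_angle(trajectory$frames[qi[1], , f],
                  trajectory$frames[qi[2], , f],
                  trajectory$frames[qi[3], , f],
                  trajectory$frames[qi[4], , f]), numeric(1))
}

#' Probability densities of side-chain dihedrals over a trajectory
#'
#' @param trajectory a `pt_trajectory`
#' @param residue_id residue to analyse
#' @param chi_indices which chi angles (default: all for the residue type)
#' @param binwidth bin width in degrees (must divide 360)
#' @return list, one element per chi, each with `breaks` (bin edges over
#'   (-180, 180]), `counts` and `density` (integrates to 1).
#' @export
dihedral_histogram <- function(trajectory, residue_id, chi_indices = NULL,
                               binwidth = 5) {
  a <- trajectory$topology$atoms
  ridx <- which(a$resid == residue_id)
  if (!length(ridx)) stop("residue ", residue_id, " not found")
  rn <- a$resname[ridx[1]]
  if (is.null(chi_indices)) chi_indices <- seq_len(n_chi(rn))
  stopifnot(360 %% binwidth == 0)
  breaks <- seq(-180, 180, by = binwidth)
  out <- lapply(chi_indices, function(k) {
    ang <- .residue_chi_series(trajectory, residue_id, k)
    # angles are in (-180, 180]; put -180-boundary values in the first bin
    cnt <- tabulate(pmin(pmax(ceiling((ang + 180) / binwidth), 1L),
                         length(breaks) - 1L),
                    nbins = length(breaks) - 1L)
    list(breaks = breaks, counts = cnt,
         density = cnt / (sum(cnt) * binwidth))
  })
  names(out) <- paste0("chi", chi_indices)
  out
}

#' Minimum side-chain distance between two residues over a trajectory
#'
#' Per-frame minimum over all pairs of side-chain atoms passing the
#' element filter (default: carbon), with mean and population SD of the
#' series.
#'
#' @param trajectory a `pt_trajectory`
#' @param residue_a,residue_b residue ids
#' @param element_filter element symbol retained on both sides
#' @return list of class `pt_contact_series`: `residue_pair`, `values`
#'   (per-frame minima, Angstrom), `mean`, `sd`.
#' @export
min_sidechain_distance <- function(trajectory, residue_a, residue_b,
                                   element_filter = "C") {
  a <- trajectory$topology$atoms
  side <- function(r) {
    idx <- which(a$resid == r & a$resname %in% .protein_resnames &
                   !(a$name %in% .backbone_names) &
                   a$element == element_filter)
    if (!length(idx))
      stop("residue ", r, " has no side-chain atoms with element ",
           element_filter)
    idx
  }
  ia <- side(residue_a); ib <- side(residue_b)
  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    xa <- matrix(trajectory$frames[ia, , f], ncol = 3)
    xb <- matrix(trajectory$frames[ib, , f], ncol = 3)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  structure(list(residue_pair = c(residue_a, residue_b), values = vals,
                 mean = mean(vals),
                 sd = sqrt(mean((vals - mean(vals))^2))),
            class = "pt_contact_series")
}
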