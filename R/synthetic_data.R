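# oscillator entropy evaluated locally so generator truth blocks stay
# independent of the estimator's code path
.osc_entropy_truth <- function(lambda_amuA2, temperature) {
  kB <- 1.380649e-23; hbar <- 1.054571817e-34
  R_kcal <- kB * 6.02214076e23 / 4184
  lambda_amuA2 <- lambda_amuA2[lambda_amuA2 > 0]
  if (!length(lambda_amuA2)) return(0)
  lam <- lambda_amuA2 * 1.66053907e-27 * 1e-20
  omega <- sqrt(kB * temperature / lam)
  x <- hbar * omega / (kB * temperature)
  sum(R_kcal * (x / expm1(x) - log1p(-exp(-x))))
}

#' Wrap bare coordinates into a carbon pseudo-structure
#'
#' One carbon atom per row, each its own residue; handy for generator
#' output and geometric tests.
#'
#' @param xyz N x 3 matrix (Angstrom)
#' @param element element symbol for all atoms
#' @return a `pt_structure`
#' @export
as_pseudo_structure <- function(xyz, element = "C") {
  n <- nrow(xyz)
  pt_structure(data.frame(
    serial = seq_len(n), name = "CA", element = element,
    resname = "ALA", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a harmonic (Gaussian) conformational ensemble
#'
#' Frames are drawn about a reference structure either with independent
#' isotropic Cartesian displacements (`sigma`, Angstrom per coordinate) or
#' in mass-weighted mode space with prescribed eigenvalues
#' (`mode_variances`, amu Angstrom^2, along orthonormal mode vectors).
#' The generator returns the closed-form quantum-oscillator internal
#' entropy of the prescribed modes as ground truth, evaluated by its own
#' local formula.
#'
#' @param reference a `pt_structure` or N x 3 coordinate matrix
#' @param n_frames number of frames
#' @param temperature K (for the entropy truth)
#' @param sigma per-coordinate Cartesian SD, Angstrom (scalar or per atom)
#' @param mode_variances eigenvalues lambda_i, amu Angstrom^2
#' @param modes optional 3N x k orthonormal mode matrix (random when
#'   omitted)
#' @param masses amu (from elements when the reference is a structure)
#' @param rotate apply a random rigid rotation + translation to every
#'   frame, to exercise external-motion removal
#' @param seed RNG seed (fixed seed implies bit-reproducible output)
#' @return list with `trajectory` (a `pt_trajectory`), `S_int_truth`
#'   (kcal/mol/K), `lambdas` (amu Angstrom^2), `modes`.
#' @export
gen_harmonic_trajectory <- function(reference, n_frames, temperature = 277,
                                    sigma = NULL, mode_variances = NULL,
                                    modes = NULL, masses = NULL,
                                    rotate = FALSE, seed = 1L) {
  if (!inherits(reference, "pt_structure"))
    reference <- as_pseudo_structure(as.matrix(reference))
  ref <- coords(reference)
  n <- nrow(ref)
  masses <- masses %||% atomic_masses(reference)
  set.seed(seed)
  if (!is.null(sigma)) {
    sig <- rep(sigma, length.out = n)
    if (any(sig < 0)) stop("sigma must be non-negative")
    lambdas <- rep(masses * sig^2, each = 3)
    disp <- function() matrix(rnorm(3 * n, sd = rep(sig, each = 3)), n, 3,
                              byrow = TRUE)
    U <- NULL
  } else if (!is.null(mode_variances)) {
    if (any(mode_variances <= 0)) stop("singular covariance")
    k <- length(mode_variances)
    if (is.null(modes)) {
      modes <- qr.Q(qr(matrix(rnorm(3 * n * k), 3 * n, k)))
    }
    U <- modes
    lambdas <- mode_variances
    sqrtl <- sqrt(mode_variances)
    invsqm <- 1 / sqrt(rep(masses, each = 3))
    disp <- function() {
      q <- U %*% (rnorm(k) * sqrtl)       # mass-weighted displacement
      matrix(q * invsqm, n, 3, byrow = TRUE)
    }
  } else stop("give either sigma or mode_variances")
  frames <- array(0, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    x <- ref + disp()
    if (rotate) {
      R <- .random_rotation()
      x <- sweep(x %*% t(R), 2, runif(3, -5, 5), "+")
    }
    frames[, , f] <- x
  }
  list(trajectory = pt_trajectory(reference, frames),
       S_int_truth = .osc_entropy_truth(lambdas, temperature),
       lambdas = sort(lambdas, decreasing = TRUE), modes = U)
}

#' Generate a Gaussian volume series with a target compressibility
#'
#' Variance is chosen as kappa * k_B * T * mean (unit-consistent), the
#' closed-form inversion of the fluctuation formula, so the estimator
#' recovers `target_kappa` in expectation.
#'
#' @param mean mean volume, Angstrom^3
#' @param target_kappa 1/GPa (> 0)
#' @param temperature K
#' @param n samples
#' @param seed RNG seed
#' @return list with `series` (a [pt_volume_series()]), `sd_truth`.
#' @export
gen_volume_series <- function(mean, target_kappa, temperature, n,
                              seed = 1L) {
  if (target_kappa <= 0) stop("target_kappa must be > 0")
  sdv <- sqrt(target_kappa * pt_constants$kB_GPa_A3 * temperature * mean)
  if (stats::pnorm(0, mean, sdv) > 1e-6)
    stop("variance would produce negative volumes with probability > 1e-6")
  set.seed(seed)
  list(series = pt_volume_series(rnorm(n, mean, sdv), temperature),
       sd_truth = sdv)
}

# minimal charged-group atom stubs; positions are offsets from a base point
.residue_stubs <- list(
  LYS = data.frame(name = "NZ", element = "N",
                   dx = 0, dy = 0, dz = 0),
  ASP = data.frame(name = c("OD1", "OD2"), element = "O",
                   dx = c(0, 0), dy = 0, dz = c(0, 2.2)),
  GLU = data.frame(name = c("OE1", "OE2"), element = "O",
                   dx = c(0, 0), dy = 0, dz = c(0, 2.2)),
  ARG = data.frame(name = c("NH1", "NH2", "NE"), element = "N",
                   dx = c(0, 2.3, 1.15), dy = 0, dz = c(0, 0, 2.0))
)

.build_atp_fragment <- function(origin = c(0, 0, 0), resid = 400L,
                                serial0 = 1000L) {
  deg <- pi / 180
  tet <- 109.47 * deg
  gdir <- function(az) c(sin(tet) * cos(az * deg), sin(tet) * sin(az * deg),
                         cos(tet))
  pos <- list(
    PG = c(0, 0, 0),
    O1G = 1.5 * gdir(0), O2G = 1.5 * gdir(120), O3G = 1.5 * gdir(240),
    O3B = c(0, 0, 1.6),
    PB = c(0, 0, 3.2),
    O1B = c(0, 0, 3.2) + c(1.5, 0, 0), O2B = c(0, 0, 3.2) + c(-1.5, 0, 0),
    O3A = c(0, 0, 4.8),
    PA = c(0, 0, 6.4),
    O1A = c(0, 0, 6.4) + c(0, 1.5, 0), O2A = c(0, 0, 6.4) + c(0, -1.5, 0),
    `O5'` = c(0, 0, 8.0),
    `C5'` = c(0, 0, 9.45))
  xyz <- do.call(rbind, pos)
  xyz <- sweep(xyz, 2, origin, "+")
  data.frame(serial = serial0 + seq_along(pos) - 1L,
             name = names(pos),
             element = substr(names(pos), 1, 1),
             resname = "ATP", resid = resid, chain = "A",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.check_clashes <- function(xyz, min_d = 1) {
  if (nrow(xyz) < 2) return(invisible())
  d <- stats::dist(xyz)
  if (min(d) < min_d)
    stop("clash: placed atoms closer than ", min_d, " A")
  invisible()
}

#' Generate a salt-bridge fixture with declared ground truth
#'
#' Builds minimal charged-group structures (Lys/Arg positives, Asp/Glu
#' negatives, optionally an ATP fragment) at exact separations, together
#' with the secondary-structure labels and subdomain map declared in the
#' spec, and a truth block derived from the construction rules alone.
#'
#' @param residues data.frame with columns `resname`, `resid`, `ss`
#'   (H/E/C), `element_id` (integer, NA for coil), `subdomain`
#' @param pairs data.frame with `pos_resid`, `neg_resid`, `distance`
#'   (Angstrom, N-O separation to the first negative oxygen) and
#'   optionally `frames` (list-column of frame indices where the contact
#'   is formed; all frames when absent)
#' @param atp optional list `(pos_resid, tag, distance, frames)` placing
#'   the positive residue's charged atom at `distance` from one terminal
#'   oxygen of the tagged ATP phosphate (`"alpha"`, `"beta"`, `"gamma"`)
#' @param n_frames number of frames (default 1)
#' @param cutoff the detection cutoff the truth block assumes
#' @param spacing base-point spacing between residues, Angstrom
#' @return list: `trajectory`, `config` (ss labels + subdomain ranges for
#'   [annotate_topology()]), `ss_profile`, `subdomains`, and `truth`
#'   (expected per-frame category counts, ATP tag, formation rates).
#' @export
gen_interaction_fixture <- function(residues, pairs = NULL, atp = NULL,
                                    n_frames = 1L, cutoff = 3.2,
                                    spacing = 30) {
  nr <- nrow(residues)
  base <- cbind(spacing * seq_len(nr), 0, 0)
  rows <- list(); serial <- 0L
  base_of <- setNames(seq_len(nr), residues$resid)
  for (i in seq_len(nr)) {
    stub <- .residue_stubs[[residues$resname[i]]]
    if (is.null(stub)) stop("unsupported fixture residue ",
                            residues$resname[i])
    for (k in seq_len(nrow(stub))) {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = stub$name[k], element = stub$element[k],
        resname = residues$resname[i], resid = residues$resid[i],
        chain = "A",
        x = base[i, 1] + stub$dx[k], y = base[i, 2] + stub$dy[k],
        z = base[i, 3] + stub$dz[k], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atp_atoms <- NULL
  if (!is.null(atp)) {
    pb <- base[base_of[as.character(atp$pos_resid)], ]
    # orient the fragment so the tagged terminal oxygen points back at
    # the positive atom and the rest of the chain leads away, then place
    # that oxygen `distance` along +y from the positive atom
    tag_atom <- c(alpha = "O1A", beta = "O1B", gamma = "O1G")[atp$tag]
    tag_p <- c(alpha = "PA", beta = "PB", gamma = "PG")[atp$tag]
    frag <- .build_atp_fragment(origin = c(0, 0, 0),
                                serial0 = serial + 1L)
    fxyz <- as.matrix(frag[, c("x", "y", "z")])
    o_t <- fxyz[frag$name == tag_atom, ]
    p_t <- fxyz[frag$name == tag_p, ]
    v <- p_t - o_t
    R <- t(.orthonormal_frame(c(0, 1, 0))) %*% .orthonormal_frame(v)
    tgt <- pb + c(0, atp$distance, 0)
    fxyz <- sweep(sweep(fxyz, 2, o_t) %*% t(R), 2, tgt, "+")
    frag$x <- fxyz[, 1]; frag$y <- fxyz[, 2]; frag$z <- fxyz[, 3]
    atp_atoms <- frag
    atoms <- rbind(atoms, frag)
  }
  struct <- pt_structure(atoms)
  .check_clashes(coords(struct))
  # place each paired residue's first negative oxygen at the set distance,
  # then push non-formed contacts away per frame
  frames <- array(0, dim = c(nrow(atoms), 3, n_frames))
  pair_frames <- list()
  if (!is.null(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      pi_ <- which(atoms$resid == pairs$pos_resid[p] &
                     atoms$element == "N")[1]
      ni <- which(atoms$resid == pairs$neg_resid[p] &
                    atoms$element == "O")[1]
      # translate the whole negative residue so its first O sits at the
      # requested distance from the positive atom, along +y where no
      # other stub atom lies
      tgt <- unlist(atoms[pi_, c("x", "y", "z")]) +
        c(0, pairs$distance[p], 0)
      dd <- tgt - unlist(atoms[ni, c("x", "y", "z")])
      idx <- which(atoms$resid == pairs$neg_resid[p])
      atoms[idx, c("x", "y", "z")] <-
        sweep(as.matrix(atoms[idx, c("x", "y", "z")]), 2, dd, "+")
      pair_frames[[p]] <- if (!is.null(pairs$frames))
        pairs$frames[[p]] else seq_len(n_frames)
    }
  }
  xyz0 <- as.matrix(atoms[, c("x", "y", "z")])
  for (f in seq_len(n_frames)) {
    x <- xyz0
    if (!is.null(pairs)) for (p in seq_len(nrow(pairs))) {
      if (!(f %in% pair_frames[[p]])) {
        idx <- which(atoms$resid == pairs$neg_resid[p])
        x[idx, 2] <- x[idx, 2] + 10    # break the contact
      }
    }
    if (!is.null(atp) && !is.null(atp$frames) && !(f %in% atp$frames)) {
      idx <- which(atoms$resname == "ATP")
      x[idx, 2] <- x[idx, 2] + 10
    }
    frames[, , f] <- x
  }
  topo <- pt_structure(atoms)
  traj <- pt_trajectory(topo, frames, frame_interval = 1)
  # declared annotations
  ss_labels <- setNames(as.character(residues$ss), residues$resid)
  eid <- setNames(as.integer(residues$element_id), residues$resid)
  ss_profile <- structure(list(labels = ss_labels, element_id = eid),
                          class = "pt_ss_profile")
  sdm <- setNames(as.integer(residues$subdomain),
                  residues$resid)
  ranges <- lapply(sort(unique(residues$subdomain)), function(s)
    residues$resid[residues$subdomain == s])
  names(ranges) <- sort(unique(residues$subdomain))
  # truth block, from the declared placements only
  classify_pair <- function(p) {
    ra <- residues[residues$resid == pairs$pos_resid[p], ]
    rb <- residues[residues$resid == pairs$neg_resid[p], ]
    both <- ra$ss %in% c("H", "E") && rb$ss %in% c("H", "E")
    ssc <- if (both && !is.na(ra$element_id) &&
                 ra$element_id == rb$element_id) "intra_helix_strand"
    else if (both) "inter_helix_strand"
    else if (ra$ss == "C" && rb$ss == "C") "loop_loop"
    else "helix_strand_loop"
    sdc <- if (ra$subdomain == rb$subdomain) "intra" else "inter"
    c(ss = ssc, sd = sdc)
  }
  per_frame_truth <- lapply(seq_len(n_frames), function(f) {
    cats <- c(inter_helix_strand = 0, helix_strand_loop = 0,
              loop_loop = 0, intra_helix_strand = 0)
    sdc <- c(inter = 0, intra = 0); natp <- 0
    if (!is.null(pairs)) for (p in seq_len(nrow(pairs))) {
      if (pairs$distance[p] <= cutoff && f %in% pair_frames[[p]]) {
        cl <- classify_pair(p)
        cats[cl["ss"]] <- cats[cl["ss"]] + 1
        sdc[cl["sd"]] <- sdc[cl["sd"]] + 1
      }
    }
    if (!is.null(atp) && atp$distance <= cutoff &&
          (is.null(atp$frames) || f %in% atp$frames)) natp <- 1
    list(ss = cats, subdomain = sdc, atp = natp,
         total = sum(cats) + natp)
  })
  rates <- list()
  if (!is.null(pairs)) for (p in seq_len(nrow(pairs)))
    if (pairs$distance[p] <= cutoff)
      rates[[paste0(min(pairs$pos_resid[p], pairs$neg_resid[p]), ":",
                    max(pairs$pos_resid[p], pairs$neg_resid[p]))]] <-
    length(pair_frames[[p]]) / n_frames
  if (!is.null(atp) && atp$distance <= cutoff)
    rates[[paste0(atp$pos_resid, ":ATP")]] <-
    length(atp$frames %||% seq_len(n_frames)) / n_frames
  atp_tag_truth <- if (!is.null(atp)) {
    one <- .aa1[residues$resname[residues$resid == atp$pos_resid]]
    lbl <- paste0(one, atp$pos_resid, "-O_", atp$tag)
    if (lbl %in% c("K18-O_alpha", "K18-O_beta", "K137-O_gamma")) lbl
    else "other-ATP"
  } else NULL
  list(trajectory = traj,
       config = list(ss_labels = ss_labels, subdomain_ranges = ranges,
                     nterm_charged = FALSE, cterm_charged = FALSE),
       ss_profile = ss_profile, subdomains = sdm,
       truth = list(per_frame = per_frame_truth,
                    formation_rates = rates,
                    atp_tag = atp_tag_truth))
}

.orthonormal_frame <- function(axis) {
  e1 <- axis / sqrt(sum(axis^2))
  tmp <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- tmp - sum(tmp * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1, e2, e3)
}

#' Generate an ATP/Mg active-site fixture with known geometry
#'
#' Places an ATP phosphate fragment, optionally a Mg ion with a W-type or
#' Q-type coordination shell, and water oxygens at requested (theta, d)
#' positions relative to the gamma-phosphorus (theta measured from the
#' beta-gamma bridging oxygen). The truth block reports every water's
#' constructed (theta, d), the expected nucleophile under the
#' minimum-distance rule with the strict theta threshold, and the shell
#' pattern label.
#'
#' @param waters data.frame with `theta` (degrees) and `d` (Angstrom);
#'   may be empty
#' @param shell NULL, `"W"` (4 waters + 2 gamma-O) or `"Q"` (3 waters +
#'   2 gamma-O + Gln side-chain O)
#' @param theta_min eligibility threshold used for the truth (degrees,
#'   strict)
#' @param mg_dist Mg-ligand distance for the shell, Angstrom
#' @return list: `structure` (a `pt_structure`), `truth` (data.frame of
#'   all water geometries, `expected_water_resid` or NA, `pattern`).
#' @export
gen_active_site_fixture <- function(waters = NULL, shell = NULL,
                                    theta_min = 109.3, mg_dist = 2.05) {
  frag <- .build_atp_fragment()
  atoms <- frag
  serial <- max(frag$serial)
  resid <- 500L
  truth_rows <- list()
  add_atom <- function(name, element, resname, rid, p) {
    serial <<- serial + 1L
    atoms <<- rbind(atoms, data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resid = rid, chain = "A", x = p[1], y = p[2], z = p[3],
      stringsAsFactors = FALSE))
  }
  pg <- c(0, 0, 0)
  u_beta <- c(0, 0, 1)                      # P_gamma -> bridging O axis
  geom_of <- function(p) {
    v <- p - pg; d <- sqrt(sum(v^2))
    th <- acos(pmin(1, pmax(-1, sum(u_beta * v) / d))) * 180 / pi
    c(theta = th, d = d)
  }
  if (!is.null(shell)) {
    o1 <- unlist(frag[frag$name == "O1G", c("x", "y", "z")])
    o2 <- unlist(frag[frag$name == "O2G", c("x", "y", "z")])
    # Mg on the bisector of the two gamma oxygens, at mg_dist from both
    m <- (o1 + o2) / 2; mdir <- m / sqrt(sum(m^2))
    # solve |t*mdir - o1| = mg_dist
    b <- -2 * sum(mdir * o1); cc <- sum(o1^2) - mg_dist^2
    t <- (-b + sqrt(b^2 - 4 * cc)) / 2
    mg <- t * mdir
    add_atom("MG", "MG", "MG", 600L, mg)
    fr <- .orthonormal_frame(mg - pg)
    sites <- list(mg + mg_dist * fr[2, ], mg - mg_dist * fr[2, ],
                  mg + mg_dist * fr[3, ], mg - mg_dist * fr[3, ])
    n_wat <- if (shell == "W") 4L else 3L
    for (s in seq_len(n_wat)) {
      resid <- resid + 1L
      add_atom("O", "O", "HOH", resid, sites[[s]])
      g <- geom_of(sites[[s]])
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(water_resid = resid, theta = g["theta"], d_nu = g["d"])
    }
    if (shell == "Q") add_atom("OE1", "O", "GLN", 137L, sites[[4]])
  }
  if (!is.null(waters) && nrow(waters)) {
    deg <- pi / 180
    for (k in seq_len(nrow(waters))) {
      th <- waters$theta[k] * deg
      az <- (40 * k) * deg
      p <- pg + waters$d[k] * c(sin(th) * cos(az), sin(th) * sin(az),
                                cos(th))
      resid <- resid + 1L
      add_atom("O", "O", "HOH", resid, p)
      g <- geom_of(p)
      if (abs(g["theta"] - waters$theta[k]) > 1e-6 ||
            abs(g["d"] - waters$d[k]) > 1e-6)
        stop("infeasible geometry for water ", k)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(water_resid = resid, theta = g["theta"], d_nu = g["d"])
    }
  }
  struct <- pt_structure(atoms)
  .check_clashes(coords(struct))
  tw <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(water_resid = integer(0), theta = numeric(0),
               d_nu = numeric(0))
  elig <- tw[tw$theta > theta_min, , drop = FALSE]
  expected <- if (nrow(elig))
    elig$water_resid[order(elig$d_nu, elig$water_resid)][1] else NA_integer_
  pattern <- if (is.null(shell)) NA_character_
  else if (shell == "W") "W-type" else "Q-type"
  list(structure = struct,
       truth = list(waters = tw, expected_water_resid = expected,
                    pattern = pattern))
}

#' Generate a Born ion system with its closed-form solvation energy
#'
#' A single spherical ion of the given charge and radius; the truth is
#' the Born expression -166.03 q^2 (1 - 1/eps_out) / radius kcal/mol
#' (interior permittivity 1).
#'
#' @param charge elementary charges
#' @param radius Angstrom (> 0)
#' @param eps_out exterior permittivity
#' @return list: `structure`, `radii` (radius table containing the ion
#'   class), `truth` (kcal/mol).
#' @export
gen_born_system <- function(charge, radius, eps_out = 80) {
  if (radius <= 0) stop("radius must be positive")
  atoms <- data.frame(serial = 1L, name = "ION", element = "X",
                      resname = "ION", resid = 1L, chain = "A",
                      x = 0, y = 0, z = 0, charge = charge,
                      radius_class = "born_ion")
  truth <- -pt_constants$coulomb_kcal / 2 * charge^2 *
    (1 - 1 / eps_out) / radius
  list(structure = pt_structure(atoms),
       radii = c(default_radius_table(), born_ion = radius),
       truth = truth)
}

#' Build an ideal polyalanine backbone at fixed (phi, psi)
#'
#' Natural-extension construction with ideal bond lengths and angles and
#' omega fixed at 180 degrees; used to make canonical helix and strand
#' fixtures for the secondary-structure assigner.
#'
#' @param n_res number of residues
#' @param phi,psi backbone dihedrals, degrees (recycled)
#' @param resname residue name for all residues
#' @return a `pt_structure` with N, CA, C atoms per residue.
#' @export
build_peptide <- function(n_res, phi, psi, resname = "ALA") {
  phi <- rep(phi, length.out = n_res)
  psi <- rep(psi, length.out = n_res)
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  pos[["C1"]] <- pos[["CA1"]] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1L)) {
    Np <- pos[[paste0("N", i)]]; CAp <- pos[[paste0("CA", i)]]
    Cp <- pos[[paste0("C", i)]]
    Nn <- place_atom(Np, CAp, Cp, 1.329, 116.2, psi[i])
    CAn <- place_atom(CAp, Cp, Nn, 1.458, 121.7, 180)
    Cn <- place_atom(Cp, Nn, CAn, 1.525, 111.2, phi[i + 1])
    pos[[paste0("N", i + 1)]] <- as.vector(Nn)
    pos[[paste0("CA", i + 1)]] <- as.vector(CAn)
    pos[[paste0("C", i + 1)]] <- as.vector(Cn)
  }
  nm <- names(pos)
  atoms <- data.frame(
    serial = seq_along(pos),
    name = sub("[0-9]+$", "", nm),
    element = substr(nm, 1, 1),
    resname = resname,
    resid = as.integer(sub("^[A-Z]+", "", nm)),
    chain = "A",
    x = vapply(pos, `[`, numeric(1), 1),
    y = vapply(pos, `[`, numeric(1), 2),
    z = vapply(pos, `[`, numeric(1), 3),
    stringsAsFactors = FALSE)
  pt_structure(atoms)
}

#' Build a rigid water molecule
#'
#' @param origin oxygen position
#' @param direction unit-ish vector: the H-H bisector (default) or, with
#'   `point_h1 = TRUE`, the exact O-H1 bond direction (for building
#'   linear hydrogen-bond donors)
#' @param resid residue id
#' @param serial0 first atom serial
#' @param point_h1 orient H1 along `direction` instead of the bisector
#' @return data.frame of three atom rows (O, H1, H2).
#' @export
gen_water_molecule <- function(origin, direction = c(1, 0, 0),
                               resid = 900L, serial0 = 9000L,
                               point_h1 = FALSE) {
  fr <- .orthonormal_frame(direction)
  if (point_h1) {
    full <- 104.52 * pi / 180
    h1 <- origin + 0.9572 * fr[1, ]
    h2 <- origin + 0.9572 * (cos(full) * fr[1, ] + sin(full) * fr[2, ])
  } else {
    half <- 104.52 / 2 * pi / 180
    h1 <- origin + 0.9572 * (cos(half) * fr[1, ] + sin(half) * fr[2, ])
    h2 <- origin + 0.9572 * (cos(half) * fr[1, ] - sin(half) * fr[2, ])
  }
  data.frame(serial = serial0 + 0:2, name = c("O", "H1", "H2"),
             element = c("O", "H", "H"), resname = "HOH", resid = resid,
             chain = "W",
             x = c(origin[1], h1[1], h2[1]),
             y = c(origin[2], h1[2], h2[2]),
             z = c(origin[3], h1[3], h2[3]), stringsAsFactors = FALSE)
}
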