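#' @useDynLib presstraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var rnorm runif setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "3MH"  # CHARMM His tautomers + 3-methylhistidine alias
)

.backbone_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

#' Construct a molecular structure
#'
#' A structure is an ordered atom table plus an optional simulation-box
#' volume. Coordinates are in Angstrom, residue numbering is 1-based and
#' taken from the source PDB.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z` and optionally `charge`
#'   (elementary charges, used by the synthetic nonbonded evaluator).
#' @param box_volume optional simulation-box volume in Angstrom^3.
#' @return An object of class `pt_structure`.
#' @export
pt_structure <- function(atoms, box_volume = NULL) {
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("empty-input error: structure has zero atoms")
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$resid < 1L)) stop("residue ids must be >= 1")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box_volume = box_volume),
            class = "pt_structure")
}

#' @export
print.pt_structure <- function(x, ...) {
  cat(sprintf("pt_structure: %d atoms, %d residues\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

#' Coordinate matrix of a structure
#' @param x a `pt_structure`
#' @return N x 3 numeric matrix (Angstrom)
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "pt_structure"))
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param x a `pt_structure`
#' @param xyz N x 3 matrix
#' @return the modified structure
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "pt_structure"), nrow(xyz) == nrow(x$atoms))
  x$atoms[, c("x", "y", "z")] <- xyz
  x
}

.element_from_name <- function(name, resname) {
  # PDB convention: element is encoded in the first alphabetic characters
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  if (two %in% c("MG", "CL", "NA", "ZN", "FE", "CA") &&
      resname %in% c("MG", "CL", "NA", "ZN", "FE", "CA")) return(two)
  first <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  if (first == "") "X" else first
}

#' Read a structure from a PDB file
#'
#' Honours ATOM/HETATM/MODEL/ENDMDL records; HETATM ligands (ATP, MG, HOH)
#' are retained with their residue names. Files containing insertion codes
#' are rejected: the pipeline assumes plain 1-based residue numbering.
#'
#' @param path path to a PDB file
#' @param model_policy `"first"` returns a single structure from the first
#'   MODEL; `"all"` returns a list of structures, one per MODEL.
#' @return A `pt_structure`, or a list of them for `model_policy = "all"`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty-input error: no atoms in ", path)
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(trimws(ins))))
    stop("insertion codes are not supported (found at serial ",
         at$eleno[which(!is.na(ins) & nzchar(trimws(ins)))[1]], ")")
  elesy <- at$elesy
  element <- vapply(seq_len(nrow(at)), function(i) {
    e <- elesy[i]
    if (!is.null(e) && !is.na(e) && nzchar(trimws(e))) toupper(trimws(e))
    else .element_from_name(at$elety[i], at$resid[i])
  }, character(1))
  base <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  mk <- function(m) {
    v <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    a <- base
    a$x <- v[, 1]; a$y <- v[, 2]; a$z <- v[, 3]
    pt_structure(a)
  }
  if (model_policy == "first") mk(1L) else lapply(seq_len(n_models), mk)
}

#' Write one or more structures to a PDB file
#'
#' Multiple structures are written as MODEL/ENDMDL blocks with identical
#' atom metadata, i.e. a multi-model ensemble file readable by
#' [read_pdb()] with `model_policy = "all"`.
#'
#' @param x a `pt_structure` or list of them (identical atom tables)
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "pt_structure")) x <- list(x)
  a <- x[[1]]$atoms
  xyz <- do.call(rbind, lapply(x, function(s) as.vector(t(coords(s)))))
  het <- !(a$resname %in% .protein_resnames)
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = ifelse(het, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, resid = a$resname, chain = a$chain,
    resno = a$resid, elesy = a$element))
  invisible(path)
}

#' Construct a trajectory
#'
#' A trajectory couples frame-invariant topology (a [pt_structure()]) with
#' per-frame coordinates and optional per-frame scalar series (box or
#' molecular volume, energy terms).
#'
#' @param topology a `pt_structure` carrying atom metadata
#' @param frames numeric array N_atoms x 3 x N_frames, or a list of N x 3
#'   matrices (Angstrom)
#' @param volumes optional numeric vector, one volume (A^3) per frame
#' @param energies optional data.frame, one row per frame; a `total` column
#'   (kcal/mol) and any named components such as `electrostatic`
#' @param frame_interval time between stored frames, ps
#' @return An object of class `pt_trajectory`.
#' @export
pt_trajectory <- function(topology, frames, volumes = NULL, energies = NULL,
                          frame_interval = 0.5) {
  stopifnot(inherits(topology, "pt_structure"))
  n <- nrow(topology$atoms)
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                            length(frames)))
  if (length(dim(frames)) != 3 || dim(frames)[2] != 3)
    stop("frames must be an N x 3 x F array")
  if (dim(frames)[1] != n)
    stop("topology error: frames have ", dim(frames)[1],
         " atoms but topology has ", n)
  nf <- dim(frames)[3]
  if (!is.null(volumes) && length(volumes) != nf)
    stop("alignment error: ", length(volumes), " volumes for ", nf, " frames")
  if (!is.null(energies) && nrow(energies) != nf)
    stop("alignment error: ", nrow(energies), " energy rows for ", nf,
         " frames")
  structure(list(topology = topology, frames = frames, volumes = volumes,
                 energies = energies, frame_interval = frame_interval),
            class = "pt_trajectory")
}

#' @export
print.pt_trajectory <- function(x, ...) {
  cat(sprintf("pt_trajectory: %d atoms x %d frames (%.3g ps interval)%s%s\n",
              dim(x$frames)[1], dim(x$frames)[3], x$frame_interval,
              if (!is.null(x$volumes)) ", volumes" else "",
              if (!is.null(x$energies)) ", energies" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a `pt_trajectory`
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' Extract one frame as a structure
#' @param x a `pt_trajectory`
#' @param i frame index
#' @return a `pt_structure`
#' @export
frame_structure <- function(x, i) set_coords(x$topology, x$frames[, , i])

#' Write trajectory frames to the package's tabular frame format
#'
#' Plain TSV with columns `frame`, `serial`, `x`, `y`, `z`; one row per
#' atom per frame. A compact text interchange format for ensembles.
#'
#' @param trajectory a `pt_trajectory`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  n <- dim(trajectory$frames)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = n),
    serial = rep(trajectory$topology$atoms$serial, nf),
    x = as.vector(trajectory$frames[, 1, ]),
    y = as.vector(trajectory$frames[, 2, ]),
    z = as.vector(trajectory$frames[, 3, ]))
  write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a trajectory from structure, frame and scalar files
#'
#' @param structure_path PDB file providing the topology (first model)
#' @param frames_path multi-model PDB, or a TSV in the format written by
#'   [write_frames_tsv()]
#' @param scalars_path optional TSV with a `frame` column, an optional
#'   `volume` column (A^3) and optional energy columns (`total`,
#'   `electrostatic`, ...), one row per frame
#' @param frame_interval ps between frames
#' @return A `pt_trajectory`; scalar columns absent from the table leave
#'   the corresponding fields unset.
#' @export
load_trajectory <- function(structure_path, frames_path,
                            scalars_path = NULL, frame_interval = 0.5) {
  topo <- read_pdb(structure_path, "first")
  n <- nrow(topo$atoms)
  if (grepl("\\.pdb$", frames_path, ignore.case = TRUE)) {
    models <- read_pdb(frames_path, "all")
    if (!is.list(models)) models <- list(models)
    counts <- vapply(models, function(s) nrow(s$atoms), integer(1))
    if (any(counts != n))
      stop("topology error: frame atom counts ",
           paste(unique(counts), collapse = "/"), " differ from topology ", n)
    frames <- array(unlist(lapply(models, coords)), dim = c(n, 3,
                                                            length(models)))
  } else {
    tab <- read.delim(frames_path)
    need <- c("frame", "serial", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("frame table must have columns: ", paste(need, collapse = ", "))
    fr <- sort(unique(tab$frame))
    per <- table(tab$frame)
    if (any(per != n))
      stop("topology error: atom count drifts across frames")
    ord <- order(tab$frame, match(tab$serial, topo$atoms$serial))
    tab <- tab[ord, ]
    frames <- array(0, dim = c(n, 3, length(fr)))
    frames[, 1, ] <- tab$x; frames[, 2, ] <- tab$y; frames[, 3, ] <- tab$z
  }
  nf <- dim(frames)[3]
  volumes <- NULL; energies <- NULL
  if (!is.null(scalars_path)) {
    sc <- read.delim(scalars_path)
    if (nrow(sc) != nf)
      stop("alignment error: ", nrow(sc), " scalar rows for ", nf, " frames")
    if (!is.null(sc$frame)) sc <- sc[order(sc$frame), , drop = FALSE]
    if ("volume" %in% names(sc)) volumes <- sc$volume
    ecols <- setdiff(names(sc), c("frame", "volume"))
    if (length(ecols)) energies <- sc[, ecols, drop = FALSE]
  }
  pt_trajectory(topo, frames, volumes = volumes, energies = energies,
                frame_interval = frame_interval)
}

#' Default actin subdomain residue ranges
#'
#' The four-lobe decomposition of the actin monomer used for inter- vs
#' intra-subdomain classification and the propeller angle. Boundaries are
#' consistent with the hinge residues 141-142 and 336-337; override via the
#' `subdomain_ranges` config entry.
#'
#' @return A list of four integer vectors of residue ids (SD1..SD4).
#' @export
default_subdomain_ranges <- function() {
  list(`1` = c(1:32, 70:141, 338:375),
       `2` = 33:69,
       `3` = c(142:180, 270:337),
       `4` = 181:269)
}

#' Map residues to subdomains
#'
#' @param resids integer residue ids (protein residues)
#' @param ranges list of integer vectors as in [default_subdomain_ranges()]
#' @return named integer vector: subdomain index per residue id.
#' @export
subdomain_map <- function(resids, ranges = default_subdomain_ranges()) {
  resids <- sort(unique(resids))
  sd <- rep(NA_integer_, length(resids))
  for (k in seq_along(ranges)) {
    hit <- resids %in% ranges[[k]]
    if (any(hit & !is.na(sd)))
      stop("subdomain ranges overlap at residue ",
           resids[which(hit & !is.na(sd))[1]])
    sd[hit] <- as.integer(names(ranges)[k] %||% k)
  }
  if (anyNA(sd))
    stop("mapping error: residue ", resids[which(is.na(sd))[1]],
         " falls outside all subdomain ranges")
  setNames(sd, resids)
}

# Side-chain charged-atom templates: name -> sign
.charged_templates <- list(
  ASP = c(OD1 = -1, OD2 = -1),
  GLU = c(OE1 = -1, OE2 = -1),
  LYS = c(NZ = +1),
  ARG = c(NH1 = +1, NH2 = +1, NE = +1)
)
.his_protonated_template <- c(ND1 = +1, NE2 = +1)

.bond_pairs <- function(xyz, max_d) {
  # all pairs within max_d; xyz small (ligand-sized)
  d <- as.matrix(stats::dist(xyz))
  which(d > 0 & d <= max_d, arr.ind = TRUE)
}

# Tag ATP phosphate oxygens alpha/beta/gamma by P-O connectivity.
# Returns data.frame(index, tag, bridging) over atom indices of the ATP
# residue within the full structure.
.tag_atp_oxygens <- function(atoms, idx) {
  sub <- atoms[idx, ]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  isP <- sub$element == "P"
  isO <- sub$element == "O"
  isC <- sub$element == "C"
  if (sum(isP) < 1L) stop("ATP residue has no phosphorus atoms")
  pb <- .bond_pairs(xyz, 1.9)
  nb <- function(i) unique(pb[pb[, 1] == i, 2])
  Ps <- which(isP)
  # order the phosphate chain: P_alpha is bonded (via an oxygen) to carbon
  p_rank <- vapply(Ps, function(p) {
    os <- intersect(nb(p), which(isO))
    any(vapply(os, function(o) any(isC[nb(o)]), logical(1)))
  }, logical(1))
  if (sum(p_rank) != 1L) {
    # fall back to name-based ordering (PA/PB/PG)
    ord <- order(match(sub$name[Ps], c("PA", "PB", "PG")))
    chain <- Ps[ord]
  } else {
    chain <- Ps[which(p_rank)]
    while (length(chain) < length(Ps)) {
      last <- chain[length(chain)]
      bridges <- intersect(nb(last), which(isO))
      nxt <- setdiff(unlist(lapply(bridges, function(o)
        intersect(nb(o), Ps))), chain)
      if (!length(nxt)) break
      chain <- c(chain, nxt[1])
    }
  }
  tags <- c("alpha", "beta", "gamma")[seq_along(chain)]
  out <- list()
  for (k in seq_along(chain)) {
    os <- intersect(nb(chain[k]), which(isO))
    for (o in os) {
      bonded_p <- intersect(nb(o), Ps)
      bridging <- length(bonded_p) > 1L || any(isC[nb(o)])
      # a bridging oxygen belongs to the earlier phosphate in the chain;
      # record it once, at the lower tag, flagged bridging
      tagk <- tags[min(match(bonded_p, chain))]
      out[[length(out) + 1L]] <- data.frame(
        index = idx[o], tag = tagk, bridging = bridging)
    }
  }
  out <- unique(do.call(rbind, out))
  out[order(out$index), ]
}

#' Annotate a structure's topology
#'
#' Identifies charged atoms (Asp/Glu carboxylate oxygens, Lys N-zeta,
#' Arg guanidinium nitrogens, protonated-His ring nitrogens, chain termini,
#' ATP phosphate oxygens tagged alpha/beta/gamma by phosphorus
#' connectivity), hydrogen-bond donors and acceptors, the subdomain map and
#' per-residue secondary-structure labels.
#'
#' @param structure a `pt_structure`
#' @param config list of options: `subdomain_ranges` (see
#'   [default_subdomain_ranges()]); `ss_labels` (named character vector of
#'   H/E/C per residue id; computed by [assign_secondary_structure()] when
#'   absent and backbone atoms exist); `protonated_his` (integer resids to
#'   treat as charged; 3MH residues are always protonated);
#'   `nterm_charged`/`cterm_charged` (logicals, default TRUE; set
#'   `nterm_charged = FALSE` for acetylated N-termini, in which case the
#'   N-terminal carboxylate of an acetyl-aspartate still enters via its
#'   Asp template).
#' @return A list of class `pt_topology` with elements `charged`
#'   (data.frame: index, serial, resname, resid, chain, name, sign, tag),
#'   `donors` (data.frame: donor index, hydrogen index), `acceptors`
#'   (integer atom indices), `subdomains` (named integer vector),
#'   `ss_labels` (named character vector), `atp_bridge_beta_gamma`
#'   (atom index of the beta-gamma bridging oxygen, or NA).
#' @export
annotate_topology <- function(structure, config = list()) {
  a <- structure$atoms
  prot <- a$resname %in% .protein_resnames
  charged <- list()
  add <- function(i, sign, tag = "sidechain") {
    charged[[length(charged) + 1L]] <<- data.frame(
      index = i, serial = a$serial[i], resname = a$resname[i],
      resid = a$resid[i], chain = a$chain[i], name = a$name[i],
      sign = sign, tag = tag, stringsAsFactors = FALSE)
  }
  protonated_his <- config$protonated_his %||% integer(0)
  res_keys <- unique(paste(a$chain, a$resid)[prot])
  unknown <- unique(a$resname[!prot & !(a$resname %in%
                                          c("ATP", "MG", "HOH", "TIP", "WAT",
                                            "SOL", "CA", "K", "CL", "NA"))])
  if (length(unknown))
    warning("unknown residue name(s) excluded from charged set: ",
            paste(unknown, collapse = ", "))
  for (key in res_keys) {
    ki <- which(paste(a$chain, a$resid) == key & prot)
    rn <- a$resname[ki[1]]
    tmpl <- .charged_templates[[rn]]
    if (rn %in% c("HIS", "HSP", "HSD", "HSE", "3MH")) {
      if (rn %in% c("HSP", "3MH") || a$resid[ki[1]] %in% protonated_his)
        tmpl <- .his_protonated_template
    }
    if (!is.null(tmpl))
      for (nm in names(tmpl)) {
        j <- ki[a$name[ki] == nm]
        if (length(j)) add(j[1], unname(tmpl[nm]))
      }
  }
  # termini, per chain
  for (ch in unique(a$chain[prot])) {
    ci <- which(prot & a$chain == ch)
    rfirst <- min(a$resid[ci]); rlast <- max(a$resid[ci])
    if (config$nterm_charged %||% TRUE) {
      j <- ci[a$resid[ci] == rfirst & a$name[ci] == "N"]
      if (length(j)) add(j[1], +1, tag = "n_terminus")
    }
    if (config$cterm_charged %||% TRUE) {
      for (nm in c("OXT", "OT1", "OT2")) {
        j <- ci[a$resid[ci] == rlast & a$name[ci] == nm]
        if (length(j)) add(j[1], -1, tag = "c_terminus")
      }
    }
  }
  atp_bridge <- NA_integer_
  atp_idx <- which(a$resname == "ATP")
  if (length(atp_idx)) {
    tg <- .tag_atp_oxygens(a, atp_idx)
    term <- tg[!tg$bridging, ]
    for (r in seq_len(nrow(term)))
      add(term$index[r], -1, tag = paste0("atp_", term$tag[r]))
    bg <- tg$index[tg$bridging & tg$tag == "beta"]
    if (length(bg)) atp_bridge <- bg[1]
    for (t in c("alpha", "beta", "gamma"))
      if (!any(term$tag == t))
        stop("ATP present but no terminal ", t, "-oxygen identified")
  }
  charged <- if (length(charged)) do.call(rbind, charged) else
    data.frame(index = integer(0), serial = integer(0),
               resname = character(0), resid = integer(0),
               chain = character(0), name = character(0),
               sign = numeric(0), tag = character(0))
  # hydrogen-bond donors (heavy atom with attached H) and acceptors
  xyz <- coords(structure)
  isH <- a$element == "H"
  heavyNO <- which(a$element %in% c("N", "O", "S"))
  donors <- list()
  for (i in heavyNO) {
    hs <- which(isH)
    if (!length(hs)) break
    d2 <- (xyz[hs, 1] - xyz[i, 1])^2 + (xyz[hs, 2] - xyz[i, 2])^2 +
      (xyz[hs, 3] - xyz[i, 3])^2
    att <- hs[d2 <= 1.25^2]
    for (h in att)
      donors[[length(donors) + 1L]] <- data.frame(donor = i, hydrogen = h)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else
    data.frame(donor = integer(0), hydrogen = integer(0))
  acceptors <- which(a$element %in% c("O", "N"))
  sdm <- if (any(prot))
    subdomain_map(unique(a$resid[prot]),
                  config$subdomain_ranges %||% default_subdomain_ranges())
  else setNames(integer(0), character(0))
  ss <- config$ss_labels
  if (is.null(ss) && any(prot) &&
      all(c("N", "CA", "C") %in% a$name[prot])) {
    prof <- tryCatch(assign_secondary_structure(structure),
                     error = function(e) NULL)
    if (!is.null(prof)) ss <- prof$labels
  }
  structure(list(charged = charged, donors = donors, acceptors = acceptors,
                 subdomains = sdm, ss_labels = ss,
                 atp_bridge_beta_gamma = atp_bridge),
            class = "pt_topology")
}
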