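.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
          HSD = "H", HSE = "H", HSP = "H", `3MH` = "H")

#' Assign secondary structure from backbone dihedrals
#'
#' A simple phi/psi-window assigner: helix when phi in [-100, -30] and psi
#' in [-80, -5]; strand when phi in [-180, -40] and psi in [90, 180] or
#' [-180, -170]; otherwise coil. Helix runs shorter than 4 residues and
#' strand runs shorter than 3 are demoted to coil. An externally supplied
#' per-residue annotation takes precedence over the computed one.
#'
#' @param structure a `pt_structure` with backbone atoms
#' @param external optional named character vector (H/E/C by residue id);
#'   returned as the profile when given
#' @param min_run named lengths for H and E runs
#' @return list of class `pt_ss_profile` with `labels` (named character,
#'   H/E/C by residue id) and `element_id` (named integer; a distinct id
#'   per contiguous H or E run, NA for coil).
#' @export
assign_secondary_structure <- function(structure, external = NULL,
                                       min_run = c(H = 4L, E = 3L)) {
  a <- structure$atoms
  prot <- which(a$resname %in% .protein_resnames)
  resids <- sort(unique(a$resid[prot]))
  if (!is.null(external)) {
    lab <- external[as.character(resids)]
    lab[is.na(lab)] <- "C"
    names(lab) <- resids
  } else {
    xyz <- coords(structure)
    bb <- function(r, nm) {
      j <- prot[a$resid[prot] == r & a$name[prot] == nm]
      if (length(j)) xyz[j[1], ] else NULL
    }
    lab <- setNames(rep("C", length(resids)), resids)
    for (k in seq_along(resids)) {
      r <- resids[k]
      N <- bb(r, "N"); CA <- bb(r, "CA"); C <- bb(r, "C")
      Cm <- if (k > 1 && resids[k - 1] == r - 1) bb(r - 1, "C") else NULL
      Np <- if (k < length(resids) && resids[k + 1] == r + 1)
        bb(r + 1, "N") else NULL
      if (is.null(N) || is.null(CA) || is.null(C)) {
        warning("missing backbone atom in residue ", r, "; labelled C")
        next
      }
      if (is.null(Cm) || is.null(Np)) next  # chain ends stay coil
      phi <- torsion_angle(Cm, N, CA, C)
      psi <- torsion_angle(N, CA, C, Np)
      if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5)
        lab[k] <- "H"
      else if (phi >= -180 && phi <= -40 &&
                 ((psi >= 90 && psi <= 180) || (psi >= -180 && psi <= -170)))
        lab[k] <- "E"
    }
    # enforce minimum run lengths
    rl <- rle(unname(lab))
    for (t in c("H", "E")) {
      short <- rl$values == t & rl$lengths < min_run[[t]]
      rl$values[short] <- "C"
    }
    lab <- setNames(inverse.rle(rl), resids)
  }
  rl <- rle(unname(lab))
  eid <- rep(NA_integer_, length(lab))
  id <- 0L; pos <- 1L
  for (g in seq_along(rl$values)) {
    idx <- pos:(pos + rl$lengths[g] - 1L)
    if (rl$values[g] %in% c("H", "E")) { id <- id + 1L; eid[idx] <- id }
    pos <- pos + rl$lengths[g]
  }
  structure(list(labels = lab, element_id = setNames(eid, resids)),
            class = "pt_ss_profile")
}

#' Detect salt bridges in one frame
#'
#' A salt bridge is any (positively charged nitrogen, negatively charged
#' oxygen) atom pair at distance less than or equal to `cutoff`; multiple
#' bridges between one residue pair are all counted. ATP phosphate oxygens
#' participate as negatives carrying their alpha/beta/gamma tag.
#'
#' @param frame a `pt_structure`
#' @param annotation a `pt_topology` from [annotate_topology()]
#' @param cutoff N-O distance cutoff, Angstrom (boundary inclusive)
#' @return data.frame with one row per bridging atom pair: positive and
#'   negative atom index/name/residue, `distance`, and the negative atom's
#'   charge-group tag.
#' @export
detect_salt_bridges <- function(frame, annotation, cutoff = 3.2) {
  ch <- annotation$charged
  pos <- ch[ch$sign > 0, , drop = FALSE]
  neg <- ch[ch$sign < 0, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg)) return(.empty_bridges())
  xyz <- coords(frame)
  P <- xyz[pos$index, , drop = FALSE]
  Nn <- xyz[neg$index, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(Nn^2), "+") - 2 * P %*% t(Nn)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(.empty_bridges())
  out <- data.frame(
    pos_index = pos$index[hit[, 1]],
    pos_name = pos$name[hit[, 1]],
    pos_resname = pos$resname[hit[, 1]],
    pos_resid = pos$resid[hit[, 1]],
    neg_index = neg$index[hit[, 2]],
    neg_name = neg$name[hit[, 2]],
    neg_resname = neg$resname[hit[, 2]],
    neg_resid = neg$resid[hit[, 2]],
    neg_tag = neg$tag[hit[, 2]],
    distance = sqrt(pmax(0, d2[hit])),
    stringsAsFactors = FALSE)
  out[order(out$pos_index, out$neg_index), ]
}

.empty_bridges <- function() {
  data.frame(pos_index = integer(0), pos_name = character(0),
             pos_resname = character(0), pos_resid = integer(0),
             neg_index = integer(0), neg_name = character(0),
             neg_resname = character(0), neg_resid = integer(0),
             neg_tag = character(0), distance = numeric(0))
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor heavy-atom distance at most
#' `dist_cutoff` and D-H...A angle (at the hydrogen) at least `angle_min`.
#' Intra-solute, solute-water and water-water bonds are labelled
#' separately.
#'
#' @param frame a `pt_structure`
#' @param annotation a `pt_topology`
#' @param dist_cutoff Angstrom
#' @param angle_min degrees
#' @return data.frame: donor, hydrogen, acceptor atom indices, `distance`,
#'   `angle`, `category`.
#' @export
detect_hbonds <- function(frame, annotation, dist_cutoff = 3.0,
                          angle_min = 160) {
  dn <- annotation$donors
  ac <- annotation$acceptors
  if (!nrow(dn) || !length(ac))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0), category = character(0)))
  a <- frame$atoms
  xyz <- coords(frame)
  iswat <- a$resname %in% c("HOH", "TIP", "WAT", "SOL")
  rows <- list()
  for (k in seq_len(nrow(dn))) {
    D <- dn$donor[k]; H <- dn$hydrogen[k]
    d2 <- rowSums(sweep(xyz[ac, , drop = FALSE], 2, xyz[D, ])^2)
    near <- ac[d2 <= dist_cutoff^2 & ac != D]
    near <- near[!(a$resid[near] == a$resid[D] &
                     a$chain[near] == a$chain[D])]
    for (A in near) {
      v1 <- xyz[D, ] - xyz[H, ]; v2 <- xyz[A, ] - xyz[H, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_min) {
        cat_ <- if (iswat[D] && iswat[A]) "water_water"
        else if (iswat[D] || iswat[A]) "solute_water"
        else "intra_solute"
        rows[[length(rows) + 1L]] <- data.frame(
          donor = D, hydrogen = H, acceptor = A,
          distance = sqrt(d2[match(A, ac)]), angle = ang, category = cat_)
      }
    }
  }
  if (!length(rows))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0), category = character(0)))
  do.call(rbind, rows)
}

#' Classify detected salt bridges
#'
#' Adds a secondary-structure category (inter-helix/strand,
#' helix/strand-loop, loop-loop, intra-helix/strand), a subdomain category
#' (inter/intra) and an ATP contact tag. Bridges involving ATP bypass the
#' secondary-structure and subdomain categories and are tagged
#' `K18-O_alpha` / `K18-O_beta` / `K137-O_gamma` when they match those
#' canonical contacts, else `other-ATP`.
#'
#' @param records data.frame from [detect_salt_bridges()]
#' @param ss a `pt_ss_profile`
#' @param subdomains named integer vector from [subdomain_map()]
#' @return the records with `ss_category`, `subdomain_category`, `atp_tag`
#'   columns added.
#' @export
classify_salt_bridges <- function(records, ss, subdomains) {
  n <- nrow(records)
  ss_cat <- rep(NA_character_, n)
  sd_cat <- rep(NA_character_, n)
  atp <- rep("none", n)
  for (i in seq_len(n)) {
    if (grepl("^atp_", records$neg_tag[i])) {
      greek <- sub("^atp_", "", records$neg_tag[i])
      one <- .aa1[records$pos_resname[i]]
      lbl <- paste0(one, records$pos_resid[i], "-O_", greek)
      atp[i] <- if (lbl %in% c("K18-O_alpha", "K18-O_beta", "K137-O_gamma"))
        lbl else "other-ATP"
      next
    }
    ra <- as.character(records$pos_resid[i])
    rb <- as.character(records$neg_resid[i])
    la <- ss$labels[ra]; lb <- ss$labels[rb]
    if (is.na(la) || is.na(lb))
      stop("classification error: residue ",
           if (is.na(la)) ra else rb, " has no secondary-structure label")
    if (is.na(subdomains[ra]) || is.na(subdomains[rb]))
      stop("classification error: residue ",
           if (is.na(subdomains[ra])) ra else rb, " has no subdomain")
    both_ss <- la %in% c("H", "E") && lb %in% c("H", "E")
    ss_cat[i] <-
      if (both_ss && ss$element_id[ra] == ss$element_id[rb])
        "intra_helix_strand"
      else if (both_ss) "inter_helix_strand"
      else if (la == "C" && lb == "C") "loop_loop"
      else "helix_strand_loop"
    sd_cat[i] <- if (subdomains[ra] == subdomains[rb]) "intra" else "inter"
  }
  records$ss_category <- ss_cat
  records$subdomain_category <- sd_cat
  records$atp_tag <- atp
  records
}

.ss_categories <- c("inter_helix_strand", "helix_strand_loop",
                    "loop_loop", "intra_helix_strand")

#' Aggregate per-frame salt-bridge records
#'
#' Per-category per-frame counts are summarised as mean and population SD;
#' per-residue-pair formation rates are the fraction of frames in which at
#' least one bridge connects the pair. Two total identities hold by
#' construction: Total = four secondary-structure categories + ATP, and
#' Total = inter-subdomain + intra-subdomain + ATP.
#'
#' @param per_frame list of classified record data.frames, one per frame
#' @param n_frames number of frames (defaults to `length(per_frame)`)
#' @return list of class `pt_interaction_summary`: `ss` and `subdomain`
#'   category statistics, `atp_contacts` (per canonical tag + Total),
#'   `total` (mean, sd), `pair_rates` data.frame, `high_rate_pairs`
#'   (formation rate > 0.5).
#' @export
aggregate_interactions <- function(per_frame, n_frames = length(per_frame)) {
  stopifnot(n_frames >= 1)
  count_cat <- function(rec, col, val, atp_only = FALSE) {
    if (!nrow(rec)) return(0L)
    if (atp_only) sum(rec$atp_tag != "none")
    else sum(!is.na(rec[[col]]) & rec[[col]] == val & rec$atp_tag == "none")
  }
  msd <- function(v) c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  ss_counts <- sapply(.ss_categories, function(cc)
    vapply(per_frame, count_cat, integer(1), col = "ss_category", val = cc))
  ss_counts <- matrix(ss_counts, nrow = length(per_frame))
  colnames(ss_counts) <- .ss_categories
  sd_counts <- sapply(c("inter", "intra"), function(cc)
    vapply(per_frame, count_cat, integer(1), col = "subdomain_category",
           val = cc))
  sd_counts <- matrix(sd_counts, nrow = length(per_frame))
  colnames(sd_counts) <- c("inter", "intra")
  atp_n <- vapply(per_frame, function(rec)
    if (nrow(rec)) sum(rec$atp_tag != "none") else 0L, integer(1))
  atp_tags <- c("K18-O_alpha", "K18-O_beta", "K137-O_gamma", "other-ATP")
  atp_counts <- sapply(atp_tags, function(tg)
    vapply(per_frame, function(rec)
      if (nrow(rec)) sum(rec$atp_tag == tg) else 0L, integer(1)))
  atp_counts <- matrix(atp_counts, nrow = length(per_frame))
  colnames(atp_counts) <- atp_tags
  total <- rowSums(ss_counts) + atp_n
  total2 <- rowSums(sd_counts) + atp_n
  if (max(abs(total - total2)) > 1e-9)
    stop("internal error: total identities disagree")
  pair_key <- function(rec) {
    if (!nrow(rec)) return(character(0))
    ifelse(rec$atp_tag != "none",
           paste0(rec$pos_resid, ":ATP"),
           paste0(pmin(rec$pos_resid, rec$neg_resid), ":",
                  pmax(rec$pos_resid, rec$neg_resid)))
  }
  keys <- lapply(per_frame, function(rec) unique(pair_key(rec)))
  all_keys <- sort(unique(unlist(keys)))
  rates <- vapply(all_keys, function(k)
    sum(vapply(keys, function(v) k %in% v, logical(1))) / n_frames,
    numeric(1))
  pair_rates <- data.frame(pair = all_keys, rate = unname(rates),
                           stringsAsFactors = FALSE)
  structure(list(
    ss = t(apply(ss_counts, 2, msd)),
    subdomain = t(apply(sd_counts, 2, msd)),
    atp_contacts = rbind(t(apply(atp_counts, 2, msd)),
                         Total = msd(atp_n)),
    total = msd(total),
    n_frames = n_frames,
    pair_rates = pair_rates,
    high_rate_pairs = pair_rates[pair_rates$rate > 0.5, , drop = FALSE]),
    class = "pt_interaction_summary")
}
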