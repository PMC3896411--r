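.water_resnames <- c("HOH", "TIP", "WAT", "SOL")

#' Mg(2+) coordination state of one frame
#'
#' Counts oxygens within `cutoff` of the single Mg ion by ligand class
#' (water, ATP phosphate by alpha/beta/gamma tag, protein side-chain
#' oxygen) and labels the shell pattern: W-type is 4 waters + 2 ATP
#' gamma-oxygens with no side-chain oxygen; Q-type is 3 waters + 2 ATP
#' gamma-oxygens + 1 side-chain oxygen; anything else is `other`.
#'
#' @param frame a `pt_structure` containing exactly one Mg
#' @param annotation a `pt_topology` (for the ATP oxygen tags)
#' @param cutoff Mg-O coordination cutoff, Angstrom
#' @return list of class `pt_coordination`: `counts` (water, atp_alpha,
#'   atp_beta, atp_gamma, sidechain), `coordination_number`, `pattern`.
#' @export
mg_coordination <- function(frame, annotation, cutoff = 2.6) {
  a <- frame$atoms
  mg <- which(a$resname == "MG" | a$element == "MG")
  if (length(mg) != 1L)
    stop("expected exactly one Mg, found ", length(mg))
  xyz <- coords(frame)
  ox <- which(a$element == "O")
  d <- sqrt(rowSums(sweep(xyz[ox, , drop = FALSE], 2, xyz[mg, ])^2))
  shell <- ox[d <= cutoff]
  tag_of <- function(i) {
    ch <- annotation$charged
    hit <- ch$tag[match(i, ch$index)]
    if (!is.na(hit) && grepl("^atp_", hit)) return(hit)
    if (a$resname[i] %in% .water_resnames) return("water")
    if (a$resname[i] == "ATP") return("atp_other")
    "sidechain"
  }
  tags <- vapply(shell, tag_of, character(1))
  counts <- c(water = sum(tags == "water"),
              atp_alpha = sum(tags == "atp_alpha"),
              atp_beta = sum(tags == "atp_beta"),
              atp_gamma = sum(tags == "atp_gamma" | tags == "atp_other"),
              sidechain = sum(tags == "sidechain"))
  cn <- length(shell)
  pattern <- if (counts["water"] == 4 && counts["atp_gamma"] == 2 &&
                   counts["sidechain"] == 0 && cn == 6) "W-type"
  else if (counts["water"] == 3 && counts["atp_gamma"] == 2 &&
             counts["sidechain"] == 1 && cn == 6) "Q-type"
  else "other"
  structure(list(counts = counts, coordination_number = cn,
                 pattern = pattern), class = "pt_coordination")
}

#' Assign the expected nucleophilic water of one frame
#'
#' For each water oxygen, theta is the angle O_beta - P_gamma - O_w (with
#' O_beta the beta-gamma bridging oxygen: the in-line attack axis opposite
#' the leaving group) and d_Nu is the P_gamma - O_w distance. Among waters
#' with theta strictly greater than `theta_min`, the one with minimum d_Nu
#' is the expected nucleophile; ties break to the lowest water residue id.
#'
#' @param frame a `pt_structure`
#' @param annotation a `pt_topology` (provides the bridging oxygen index)
#' @param theta_min eligibility threshold, degrees (strict inequality)
#' @param o_beta_index override for the reference beta oxygen atom index
#' @return list with `water_resid`, `water_index`, `theta` (degrees),
#'   `d_nu` (Angstrom), or NULL when no water is eligible.
#' @export
assign_nucleophilic_water <- function(frame, annotation,
                                      theta_min = 109.3,
                                      o_beta_index = NULL) {
  a <- frame$atoms
  pg <- which(a$resname == "ATP" & a$element == "P")
  if (!length(pg)) stop("no ATP phosphorus found")
  xyz0 <- coords(frame)
  gidx <- annotation$charged$index[annotation$charged$tag == "atp_gamma"]
  if (length(gidx)) {
    # terminal phosphorus = the one carrying the gamma-tagged oxygens
    gcen <- colMeans(xyz0[gidx, , drop = FALSE])
    pg <- pg[which.min(rowSums(sweep(xyz0[pg, , drop = FALSE], 2,
                                     gcen)^2))]
  } else pg <- pg[length(pg)]
  ob <- o_beta_index %||% annotation$atp_bridge_beta_gamma
  if (is.null(ob) || is.na(ob)) stop("beta-gamma bridging oxygen not found")
  xyz <- coords(frame)
  wat <- which(a$resname %in% .water_resnames & a$element == "O")
  if (!length(wat)) return(NULL)
  v_b <- xyz[ob, ] - xyz[pg, ]
  res <- lapply(wat, function(w) {
    v_w <- xyz[w, ] - xyz[pg, ]
    d <- sqrt(sum(v_w^2))
    th <- acos(pmin(1, pmax(-1, sum(v_b * v_w) /
                              (sqrt(sum(v_b^2)) * d)))) * 180 / pi
    c(theta = th, d_nu = d)
  })
  theta <- vapply(res, `[[`, numeric(1), "theta")
  d_nu <- vapply(res, `[[`, numeric(1), "d_nu")
  elig <- theta > theta_min
  if (!any(elig)) return(NULL)
  cand <- which(elig)
  best <- cand[order(d_nu[cand], a$resid[wat[cand]])][1]
  list(water_resid = a$resid[wat[best]], water_index = wat[best],
       theta = theta[best], d_nu = d_nu[best])
}

#' Nucleophilic-water records over a trajectory
#'
#' @param trajectory a `pt_trajectory`
#' @param annotation a `pt_topology`
#' @param theta_min degrees
#' @return data.frame with columns `frame`, `water_resid`, `theta`,
#'   `d_nu`; frames with no eligible water are omitted.
#' @export
nucleophilic_water_series <- function(trajectory, annotation,
                                      theta_min = 109.3) {
  rows <- lapply(seq_len(n_frames(trajectory)), function(f) {
    r <- assign_nucleophilic_water(frame_structure(trajectory, f),
                                   annotation, theta_min)
    if (is.null(r)) return(NULL)
    data.frame(frame = f, water_resid = r$water_resid,
               theta = r$theta, d_nu = r$d_nu)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(frame = integer(0), water_resid = integer(0),
                      theta = numeric(0), d_nu = numeric(0)))
  do.call(rbind, rows)
}

#' Binned (theta, d_Nu) free-energy surface
#'
#' Two-dimensional histogram of nucleophilic-water records converted to a
#' free-energy scale F = -ln(count / max count) in units of k_B T; the
#' occupied minimum is exactly zero and empty bins are NA.
#'
#' @param records data.frame with `theta` (degrees) and `d_nu` (Angstrom)
#' @param theta_bin,d_bin bin widths (degrees, Angstrom)
#' @param theta_range,d_range bin ranges (defaults cover the data)
#' @return list of class `pt_fes`: `theta_edges`, `d_edges`, `counts`,
#'   `free_energy` (matrices, theta rows x d columns).
#' @export
theta_d_free_energy_surface <- function(records, theta_bin = 2,
                                        d_bin = 0.1, theta_range = NULL,
                                        d_range = NULL) {
  if (!nrow(records)) stop("no records to bin")
  snap <- function(r, w) c(floor(r[1] / w) * w, ceiling(r[2] / w) * w)
  tr <- theta_range %||% snap(range(records$theta), theta_bin)
  dr <- d_range %||% snap(range(records$d_nu), d_bin)
  te <- seq(tr[1], tr[2] + theta_bin / 2, by = theta_bin)
  de <- seq(dr[1], dr[2] + d_bin / 2, by = d_bin)
  ti <- pmin(pmax(findInterval(records$theta, te,
                               rightmost.closed = TRUE), 1L),
             length(te) - 1L)
  di <- pmin(pmax(findInterval(records$d_nu, de,
                               rightmost.closed = TRUE), 1L),
             length(de) - 1L)
  counts <- matrix(0L, length(te) - 1L, length(de) - 1L)
  for (k in seq_along(ti))
    counts[ti[k], di[k]] <- counts[ti[k], di[k]] + 1L
  fe <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  fe[occ] <- log(max(counts)) - log(counts[occ])   # 0 at the mode, exactly
  structure(list(theta_edges = te, d_edges = de, counts = counts,
                 free_energy = fe), class = "pt_fes")
}

.kyte_doolittle <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

#' Kyte-Doolittle hydropathy index
#'
#' @param residue 3-letter or 1-letter amino-acid code (vectorised)
#' @return numeric hydropathy value(s); isoleucine (4.5) is the maximum.
#' @export
hydropathy_lookup <- function(residue) {
  residue <- toupper(residue)
  three <- ifelse(nchar(residue) == 1,
                  names(.aa1)[match(residue, .aa1)], residue)
  v <- .kyte_doolittle[three]
  if (anyNA(v)) stop("unknown amino-acid code: ",
                     paste(residue[is.na(v)], collapse = ", "))
  setNames(unname(v), residue)
}
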