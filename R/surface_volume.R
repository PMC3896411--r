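#' Default van der Waals radius table by hybridization class
#'
#' Heavy-atom radii follow the convention used for rolling-probe surface
#' work on proteins: 2.0 A for sp3 carbon, sp3 nitrogen and sulfur bearing
#' a hydrogen; 1.7 A for sp2 carbon without hydrogen and sp2 nitrogen with
#' one hydrogen; 1.85 A for sp2 carbon with hydrogen(s) and sulfur without
#' hydrogen; 1.8 A for sp2 nitrogen with several hydrogens; 1.4 A for
#' oxygen. Hydrogens carry no sphere (heavy atoms carry class radii).
#' Phosphorus and magnesium classes are package additions for the ATP/Mg
#' site.
#'
#' @return named numeric vector, radius class -> Angstrom.
#' @export
default_radius_table <- function() {
  c(C_sp3 = 2.0, N_sp3 = 2.0, S_H = 2.0,
    C_sp2_noH = 1.7, N_sp2_1H = 1.7,
    C_sp2_H = 1.85, S_noH = 1.85,
    N_sp2_multiH = 1.8,
    O = 1.4,
    P = 1.9, MG = 1.18,
    H = 0)
}

.c_sp2_noH <- list(
  ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = "CZ",
  PHE = "CG", TYR = c("CG", "CZ"), TRP = c("CG", "CD2", "CE2"),
  HIS = "CG", HSD = "CG", HSE = "CG", HSP = "CG", `3MH` = "CG",
  ATP = c("C4", "C5", "C6"))
.c_sp2_H <- list(
  PHE = c("CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CD1", "CD2", "CE1", "CE2"),
  TRP = c("CD1", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CD2", "CE1"), HSD = c("CD2", "CE1"), HSE = c("CD2", "CE1"),
  HSP = c("CD2", "CE1"), `3MH` = c("CD2", "CE1"),
  ATP = c("C2", "C8"))
.n_multiH <- list(
  ARG = c("NH1", "NH2"), ASN = "ND2", GLN = "NE2", ATP = "N6")

#' Assign hybridization/H-count radius classes to all atoms
#'
#' Template-based assignment covering the 20 amino acids, ATP, Mg and
#' water. Unknown atoms raise an error rather than receiving a default.
#'
#' @param structure a `pt_structure`
#' @return the structure with a `radius_class` atom column added.
#' @export
assign_radius_class <- function(structure) {
  a <- structure$atoms
  cls <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]; rn <- a$resname[i]; nm <- a$name[i]
    cls[i] <-
      if (el == "H") "H"
      else if (el == "O") "O"
      else if (el == "P") "P"
      else if (el == "MG" || rn == "MG") "MG"
      else if (el == "S") { if (nm == "SD") "S_noH" else "S_H" }
      else if (el == "N") {
        if (rn == "LYS" && nm == "NZ") "N_sp3"
        else if (nm %in% (.n_multiH[[rn]] %||% character(0)))
          "N_sp2_multiH"
        else if (nm == "N" && rn %in% .protein_resnames &&
                   a$resid[i] == min(a$resid[a$resname %in%
                                               .protein_resnames]))
          "N_sp3"  # free N-terminal amine
        else "N_sp2_1H"
      }
      else if (el == "C") {
        if (nm == "C" || nm %in% (.c_sp2_noH[[rn]] %||% character(0)))
          "C_sp2_noH"
        else if (nm %in% (.c_sp2_H[[rn]] %||% character(0))) "C_sp2_H"
        else "C_sp3"
      }
      else stop("no radius class for atom ", nm, " (", el, ") in residue ",
                rn)
  }
  structure$atoms$radius_class <- cls
  structure
}

.atom_radii <- function(structure, radii) {
  if (is.null(structure$atoms$radius_class))
    structure <- assign_radius_class(structure)
  cls <- structure$atoms$radius_class
  unknown <- setdiff(unique(cls), names(radii))
  if (length(unknown))
    stop("missing radius class(es): ", paste(unknown, collapse = ", "))
  unname(radii[cls])
}

# deterministic generalized-spiral point lattice on the unit sphere
.spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area by rolling-probe lattice integration
#'
#' Numeric integration over deterministic spiral point lattices on spheres
#' of radius r_i + probe; a lattice point counts as accessible when it lies
#' outside every other inflated sphere. Hydrogens carry no sphere.
#'
#' @param structure a `pt_structure` (radius classes assigned on the fly
#'   when absent)
#' @param radii radius table (class -> Angstrom)
#' @param probe probe radius, Angstrom
#' @param n_points lattice points per atom (>= 100)
#' @return total SASA in Angstrom^2.
#' @export
sasa <- function(structure, radii = default_radius_table(), probe = 1.4,
                 n_points = 960) {
  stopifnot(n_points >= 100)
  r <- .atom_radii(structure, radii)
  keep <- r > 0
  xyz <- coords(structure)[keep, , drop = FALSE]
  R <- r[keep] + probe
  n <- nrow(xyz)
  pts <- .spiral_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 > 0 & d2 < (R[i] + R)^2)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * mean(acc)
  }
  total
}

#' Excluded volume of the probe-inflated molecular envelope
#'
#' Volume of the union of spheres of radius r_i + probe, by grid occupancy
#' with a centroid-in-sphere test.
#'
#' @inheritParams sasa
#' @param grid_spacing grid cell edge, Angstrom (refused above 0.5)
#' @return volume in Angstrom^3.
#' @export
excluded_volume <- function(structure, radii = default_radius_table(),
                            probe = 1.4, grid_spacing = 0.25) {
  if (grid_spacing > 0.5)
    stop("grid too coarse: spacing must be <= 0.5 A, got ", grid_spacing)
  r <- .atom_radii(structure, radii)
  keep <- r > 0
  xyz <- coords(structure)[keep, , drop = FALSE]
  R <- r[keep] + probe
  h <- grid_spacing
  lo <- apply(xyz - R, 2, min) - h
  hi <- apply(xyz + R, 2, max) + h
  ax <- seq(lo[1] + h / 2, hi[1], by = h)
  ay <- seq(lo[2] + h / 2, hi[2], by = h)
  az <- seq(lo[3] + h / 2, hi[3], by = h)
  occ <- array(FALSE, dim = c(length(ax), length(ay), length(az)))
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(ax - xyz[i, 1]) <= R[i])
    iy <- which(abs(ay - xyz[i, 2]) <= R[i])
    iz <- which(abs(az - xyz[i, 3]) <= R[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    m <- outer(outer((ax[ix] - xyz[i, 1])^2, (ay[iy] - xyz[i, 2])^2, "+"),
               (az[iz] - xyz[i, 3])^2, "+")
    occ[ix, iy, iz] <- occ[ix, iy, iz] | (m <= R[i]^2)
  }
  sum(occ) * h^3
}

#' Construct a per-frame volume series
#' @param values per-frame volumes, Angstrom^3 (all > 0)
#' @param temperature absolute temperature, K
#' @return object of class `pt_volume_series`
#' @export
pt_volume_series <- function(values, temperature) {
  if (any(values <= 0)) stop("volumes must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(values = values, temperature = temperature),
            class = "pt_volume_series")
}

#' Isothermal compressibility from equilibrium volume fluctuations
#'
#' kappa_T = (<V^2> - <V>^2) / (k_B T <V>), with the averages taken over
#' the supplied series. Accepts either a simulation-box series or a
#' per-frame molecular excluded-volume series.
#'
#' @param series a [pt_volume_series()]
#' @return compressibility in 1/GPa.
#' @export
isothermal_compressibility <- function(series) {
  stopifnot(inherits(series, "pt_volume_series"))
  v <- series$values
  if (length(v) < 2L) stop("need at least 2 samples")
  varv <- mean(v^2) - mean(v)^2
  varv / (pt_constants$kB_GPa_A3 * series$temperature * mean(v))
}

#' Mean and population SD of a scalar series over a window
#'
#' The building block for "X +/- SD" reporting and pressure differences
#' Delta = X_highP - X_lowP.
#'
#' @param values numeric vector (per-frame scalars)
#' @param window integer frame indices (default: all)
#' @return named numeric vector `c(mean, sd)` (population SD).
#' @export
series_stats <- function(values, window = NULL) {
  if (!is.null(window)) values <- values[window]
  if (!length(values)) stop("empty window")
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}
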