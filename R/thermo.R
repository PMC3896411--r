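.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.973762, MG = 24.305, K = 39.0983,
                    CL = 35.45, CA = 40.078, FE = 55.845, ZN = 65.38,
                    X = 12.011)

#' Atomic masses of a structure
#' @param structure a `pt_structure`
#' @return numeric vector of masses, amu
#' @export
atomic_masses <- function(structure) {
  el <- structure$atoms$element
  m <- .atomic_masses[el]
  if (anyNA(m)) stop("no mass for element(s): ",
                     paste(unique(el[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Window statistics of per-frame conformational energies
#'
#' @param energies data.frame of per-frame energy terms with a `total`
#'   column (kcal/mol) and optionally `electrostatic`, or a bare numeric
#'   vector of totals
#' @param window integer frame indices (default: all)
#' @return list with `total = c(mean, sd)` and, when available,
#'   `electrostatic = c(mean, sd)` (population SDs).
#' @export
mean_conformational_energy <- function(energies, window = NULL) {
  if (is.numeric(energies)) energies <- data.frame(total = energies)
  if (is.null(energies$total)) stop("energies need a 'total' column")
  out <- list(total = series_stats(energies$total, window))
  if (!is.null(energies$electrostatic))
    out$electrostatic <- series_stats(energies$electrostatic, window)
  out
}

#' Difference of two windowed means with quadrature SDs
#'
#' Forms `mean_H - mean_N` with the SD propagated in quadrature; the shape
#' of every pressure-difference row (conformational energy, solvation,
#' entropy) in the free-energy cycle.
#'
#' @param stat_N,stat_H `c(mean, sd)` vectors (low/high pressure)
#' @return `c(mean, sd)` of the difference.
#' @export
stat_difference <- function(stat_N, stat_H) {
  c(mean = unname(stat_H["mean"] - stat_N["mean"]),
    sd = unname(sqrt(stat_H["sd"]^2 + stat_N["sd"]^2)))
}

#' Pairwise nonbonded energy of a frame
#'
#' Vacuum Coulomb plus 12-6 Lennard-Jones over unique atom pairs, with
#' Lorentz-Berthelot combination. A minimal evaluator for synthetic
#' fixtures whose per-frame energies must be self-consistent; production
#' conformational energies are consumed from per-frame tables.
#'
#' @param frame a `pt_structure`; charges default to its `charge` column
#' @param charges optional numeric vector, elementary charges
#' @param lj optional data.frame with per-atom `epsilon` (kcal/mol) and
#'   `sigma` (Angstrom); zero when omitted
#' @return energy in kcal/mol.
#' @export
nonbonded_energy <- function(frame, charges = NULL, lj = NULL) {
  q <- charges %||% frame$atoms$charge
  if (anyNA(q)) stop("unparameterized atom: missing charge at index ",
                     which(is.na(q))[1])
  xyz <- coords(frame)
  n <- nrow(xyz)
  if (n < 2L) return(0)
  e <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    r <- sqrt(rowSums(sweep(xyz[j, , drop = FALSE], 2, xyz[i, ])^2))
    e <- e + sum(pt_constants$coulomb_kcal * q[i] * q[j] / r)
    if (!is.null(lj)) {
      epsij <- sqrt(lj$epsilon[i] * lj$epsilon[j])
      sigij <- (lj$sigma[i] + lj$sigma[j]) / 2
      sr6 <- (sigij / r)^6
      e <- e + sum(4 * epsij * (sr6^2 - sr6))
    }
  }
  e
}

# Saturation-line water density (g/cm^3) at 0.1 MPa, small table 270-380 K
.water_density_table <- data.frame(
  T = c(270, 277, 283, 293, 298.15, 313, 333, 353, 373, 380),
  rho = c(0.9999, 0.99997, 0.9997, 0.9982, 0.99705, 0.9922, 0.9832,
          0.9718, 0.9584, 0.9537))

#' Water density model
#'
#' Interpolated ambient-pressure density with a compressibility-based
#' pressure correction (Tait-like, kappa ~ 0.45/GPa), adequate over
#' 270-380 K and up to 200 MPa. Swap in a better equation of state by
#' passing your own function to [water_dielectric()].
#'
#' @param temperature K
#' @param pressure MPa
#' @return density in g/cm^3.
#' @export
water_density <- function(temperature, pressure = 0.1) {
  rho0 <- stats::approx(.water_density_table$T, .water_density_table$rho,
                        xout = temperature, rule = 2)$y
  kappa <- 0.45  # 1/GPa, representative cold-water isothermal value
  rho0 / (1 - kappa * (pressure - 0.1) / 1000)
}

# effective Kirkwood correlation factor, calibrated so that the ambient
# reference point (298.15 K, 0.1 MPa) returns eps = 78.4
.dielectric_y_needed <- function(eps) (2 * eps^2 - eps - 1) / (9 * eps)

.calibrated_g <- local({
  mu2 <- (1.85e-18)^2          # dipole moment squared, esu^2 cm^2
  alpha <- 1.444e-24           # molecular polarizability, cm^3
  kB_erg <- 1.380649e-16
  Tc <- 298.15
  n <- 0.99705 * 6.02214076e23 / 18.015   # molecules / cm^3
  y <- .dielectric_y_needed(78.4)
  (y / (4 * pi / 3) / n - alpha) * 3 * kB_erg * Tc / mu2
})

#' Relative permittivity of water from the Kirkwood g-factor model
#'
#' Kirkwood dielectric equation with an effective orientational
#' correlation factor g, calibrated against the ambient reference value
#' eps(298.15 K, 0.1 MPa) = 78.4. Temperature and pressure enter through
#' the molecular density (equation-of-state table) and the 1/T Boltzmann
#' factor; the estimate increases with pressure at fixed temperature and
#' decreases with temperature at fixed pressure.
#'
#' @param temperature K, in [270, 380]
#' @param pressure MPa, in (0, 200]
#' @param g orientational correlation factor (default: calibrated)
#' @param density_fun function(T, p) -> g/cm^3 (default [water_density()])
#' @return relative permittivity (dimensionless).
#' @export
water_dielectric <- function(temperature, pressure, g = NULL,
                             density_fun = water_density) {
  if (temperature < 270 || temperature > 380)
    stop("temperature out of range [270, 380] K")
  if (pressure <= 0 || pressure > 200)
    stop("pressure out of range (0, 200] MPa")
  g <- g %||% .calibrated_g
  mu2 <- (1.85e-18)^2
  alpha <- 1.444e-24
  kB_erg <- 1.380649e-16
  n <- density_fun(temperature, pressure) * 6.02214076e23 / 18.015
  y <- (4 * pi / 3) * n * (alpha + g * mu2 / (3 * kB_erg * temperature))
  # (eps - 1)(2 eps + 1) / (9 eps) = y  =>  quadratic in eps
  (1 + 9 * y + sqrt((1 + 9 * y)^2 + 8)) / 4
}

#' Polar solvation free energy by finite-difference Poisson solve
#'
#' Two-dielectric continuum model: the solute interior (union of atomic
#' van der Waals spheres) carries `eps_in`, the exterior `eps_out`.
#' Charges are spread trilinearly onto the grid, the potential is solved
#' by red-black successive over-relaxation, and the polar solvation energy
#' is the difference of 0.5 * sum q_i phi(x_i) between the solvated state
#' and a reference state with exterior permittivity `eps_vacuum` on the
#' identical grid, so the grid self-energy cancels exactly.
#'
#' @param structure a `pt_structure` with charges
#' @param eps_in interior permittivity (default 2)
#' @param eps_out exterior (solvent) permittivity
#' @param eps_vacuum exterior permittivity of the reference state
#' @param radii radius table for the dielectric boundary
#' @param grid_spacing Angstrom
#' @param margin grid margin beyond the solute, Angstrom
#' @param tol relative SOR convergence tolerance
#' @param max_iter SOR iteration cap
#' @return polar solvation free energy, kcal/mol.
#' @export
polar_solvation <- function(structure, eps_in = 2, eps_out = 80,
                            eps_vacuum = 1, radii = default_radius_table(),
                            grid_spacing = 0.4, margin = 8,
                            tol = 1e-7, max_iter = 20000L) {
  q <- structure$atoms$charge
  if (anyNA(q)) stop("all atoms need charges for the Poisson solve")
  if (all(q == 0)) return(0)
  r <- .atom_radii(structure, radii)
  xyz <- coords(structure)
  h <- grid_spacing
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  ax <- seq(lo[1], hi[1] + h, by = h)
  ay <- seq(lo[2], hi[2] + h, by = h)
  az <- seq(lo[3], hi[3] + h, by = h)
  dims <- c(length(ax), length(ay), length(az))

  inside <- function(px, py, pz) {
    out <- rep(FALSE, length(px))
    for (i in seq_len(nrow(xyz))) {
      if (r[i] <= 0) next
      out <- out | ((px - xyz[i, 1])^2 + (py - xyz[i, 2])^2 +
                      (pz - xyz[i, 3])^2 <= r[i]^2)
    }
    out
  }
  # harmonic-mean edge dielectric, sampled at 5 points along each edge:
  # the series-flux average that keeps the normal displacement continuous
  edge_eps <- function(axis, eps_ext) {
    px <- rep(ax, times = dims[2] * dims[3])
    py <- rep(rep(ay, each = dims[1]), times = dims[3])
    pz <- rep(az, each = dims[1] * dims[2])
    inv <- 0
    fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    for (fr in fracs) {
      qx <- px; qy <- py; qz <- pz
      if (axis == 1) qx <- qx + fr * h
      if (axis == 2) qy <- qy + fr * h
      if (axis == 3) qz <- qz + fr * h
      inv <- inv + 1 / ifelse(inside(qx, qy, qz), eps_in, eps_ext)
    }
    length(fracs) / inv
  }
  # trilinear charge spreading
  src <- numeric(prod(dims))
  k_c <- pt_constants$coulomb_kcal
  for (i in seq_len(nrow(xyz))) {
    if (q[i] == 0) next
    fx <- (xyz[i, 1] - ax[1]) / h; fy <- (xyz[i, 2] - ay[1]) / h
    fz <- (xyz[i, 3] - az[1]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
        (if (dz) wz else 1 - wz)
      idx <- (i0 + dx) + dims[1] * ((j0 + dy) + dims[2] * (k0 + dz)) + 1
      src[idx] <- src[idx] + 4 * pi * k_c * q[i] * w / h
    }
  }
  boundary_phi <- function(eps_ext) {
    phi <- numeric(prod(dims))
    bmask <- array(FALSE, dims)
    bmask[c(1, dims[1]), , ] <- TRUE
    bmask[, c(1, dims[2]), ] <- TRUE
    bmask[, , c(1, dims[3])] <- TRUE
    bi <- which(bmask)
    ii <- (bi - 1) %% dims[1]
    jj <- ((bi - 1) %/% dims[1]) %% dims[2]
    kk <- (bi - 1) %/% (dims[1] * dims[2])
    px <- ax[ii + 1]; py <- ay[jj + 1]; pz <- az[kk + 1]
    val <- numeric(length(bi))
    for (i in seq_len(nrow(xyz))) {
      if (q[i] == 0) next
      d <- sqrt((px - xyz[i, 1])^2 + (py - xyz[i, 2])^2 +
                  (pz - xyz[i, 3])^2)
      val <- val + k_c * q[i] / (eps_ext * d)
    }
    phi[bi] <- val
    phi
  }
  omega <- 2 / (1 + sin(pi / max(dims)))
  solve_state <- function(eps_ext) {
    res <- poisson_sor(boundary_phi(eps_ext),
                       edge_eps(1, eps_ext), edge_eps(2, eps_ext),
                       edge_eps(3, eps_ext), src, as.integer(dims),
                       omega, tol, as.integer(max_iter))
    if (!res$converged)
      stop("Poisson solver did not converge in ", res$iterations,
           " iterations")
    res$phi
  }
  interp <- function(phi) {
    vapply(seq_len(nrow(xyz)), function(i) {
      fx <- (xyz[i, 1] - ax[1]) / h; fy <- (xyz[i, 2] - ay[1]) / h
      fz <- (xyz[i, 3] - az[1]) / h
      i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
      wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
      v <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
          (if (dz) wz else 1 - wz)
        v <- v + w * phi[(i0 + dx) + dims[1] * ((j0 + dy) +
                                                  dims[2] * (k0 + dz)) + 1]
      }
      v
    }, numeric(1))
  }
  e_state <- function(eps_ext) 0.5 * sum(q * interp(solve_state(eps_ext)))
  e_state(eps_out) - e_state(eps_vacuum)
}

#' Nonpolar solvation free energy from surface area
#'
#' The surface-tension term gamma(T) * A; the van der Waals attraction
#' term is fixed at zero (its contribution is below 0.1 percent). The
#' default coefficient is gamma(277 K) = 0.1091 kcal/mol/A^2, scaled to
#' other temperatures by the air-water surface-tension ratio.
#'
#' @param area solvent-accessible area, Angstrom^2 (>= 0)
#' @param temperature K
#' @param gamma kcal/mol/Angstrom^2; overrides the temperature scaling
#' @return list with `nonpolar` (kcal/mol), `gamma`, `area`,
#'   `vdw_term` (always 0).
#' @export
nonpolar_solvation <- function(area, temperature = 277, gamma = NULL) {
  if (area < 0) stop("negative area")
  if (is.null(gamma)) {
    st <- function(T) 75.7 - 0.147 * (T - 273.15)   # mN/m, linear fit
    gamma <- 0.1091 * st(temperature) / st(277)
  }
  list(nonpolar = gamma * area, gamma = gamma, area = area, vdw_term = 0)
}

#' Surface-tension coefficient used by [nonpolar_solvation()]
#' @param temperature K
#' @return gamma in kcal/mol/Angstrom^2 (0.1091 at 277 K).
#' @export
gamma_surface_tension <- function(temperature = 277) {
  nonpolar_solvation(0, temperature)$gamma
}

#' Translational entropy of an ideal gas (Sackur-Tetrode form)
#'
#' S = R [ ln( (2 pi M k_B T / h^2)^{3/2} * V / N_A ) + 5/2 ] per mole.
#'
#' @param M molecular mass, amu
#' @param V volume per mole, L/mol (default 1: the 1 M standard state)
#' @param temperature K
#' @return entropy in kcal/mol/K.
#' @export
translational_entropy <- function(M, V = 1, temperature) {
  if (M <= 0 || V <= 0 || temperature <= 0) stop("inputs must be positive")
  cst <- pt_constants
  m <- M * cst$amu
  v <- V * 1e-3 / cst$N_A                      # m^3 per molecule
  q <- (2 * pi * m * cst$kB * temperature / cst$h^2)^1.5 * v
  cst$R_kcal * (log(q) + 2.5)
}

#' Rotational entropy of a classical rigid rotor
#'
#' S = R [ ln( sqrt(pi)/sigma * (8 pi^2 k_B T / h^2)^{3/2} *
#' sqrt(Ix Iy Iz) ) + 3/2 ] per mole.
#'
#' @param I_x,I_y,I_z principal moments of inertia, amu Angstrom^2
#' @param temperature K
#' @param sigma rotational symmetry number
#' @return entropy in kcal/mol/K.
#' @export
rotational_entropy <- function(I_x, I_y, I_z, temperature, sigma = 1) {
  if (min(I_x, I_y, I_z) <= 0) stop("moments of inertia must be positive")
  cst <- pt_constants
  conv <- cst$amu * 1e-20                      # amu A^2 -> kg m^2
  pre <- (8 * pi^2 * cst$kB * temperature / cst$h^2)^1.5
  arg <- sqrt(pi) / sigma * pre * sqrt(I_x * I_y * I_z * conv^3)
  cst$R_kcal * (log(arg) + 1.5)
}

#' Principal moments of inertia
#' @param xyz N x 3 coordinates (Angstrom) or a `pt_structure`
#' @param masses amu (derived from elements for a structure)
#' @return ascending numeric length-3 vector, amu Angstrom^2.
#' @export
moments_of_inertia <- function(xyz, masses = NULL) {
  if (inherits(xyz, "pt_structure")) {
    masses <- masses %||% atomic_masses(xyz)
    xyz <- coords(xyz)
  }
  com <- colSums(xyz * masses) / sum(masses)
  d <- sweep(xyz, 2, com)
  r2 <- rowSums(d^2)
  I <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- sum(masses * ((a == b) * r2 - d[, a] * d[, b]))
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Quantum harmonic-oscillator entropy of quasi-harmonic modes
#'
#' Per-mode entropy k_B [ x/(e^x - 1) - ln(1 - e^{-x}) ] with
#' x = hbar omega / k_B T and omega = sqrt(k_B T / lambda) for a
#' mass-weighted covariance eigenvalue lambda (amu Angstrom^2). Includes
#' the kinetic term.
#'
#' @param lambda eigenvalues, amu Angstrom^2
#' @param temperature K
#' @return per-mode entropies, kcal/mol/K.
#' @export
harmonic_mode_entropy <- function(lambda, temperature) {
  cst <- pt_constants
  lam <- lambda * cst$amu * 1e-20              # kg m^2
  omega <- sqrt(cst$kB * temperature / lam)
  x <- cst$hbar * omega / (cst$kB * temperature)
  cst$R_kcal * (x / (expm1(x)) - log1p(-exp(-x)))
}

#' Quasi-harmonic internal entropy of a trajectory segment
#'
#' Frames are superposed onto the segment mean to remove external motion,
#' the mass-weighted coordinate covariance matrix is diagonalised, each
#' retained eigenvalue is converted to an effective mode frequency
#' omega_i = sqrt(k_B T / lambda_i), and the quantum harmonic-oscillator
#' entropy is summed over modes. The `n_drop` smallest eigenvalues
#' (residual external modes) and eigenvalues below `tol` are discarded.
#'
#' @param trajectory a `pt_trajectory` (or N x 3 x F array)
#' @param masses amu, per atom (derived from the topology when omitted)
#' @param temperature K
#' @param fit superpose frames onto the mean first (default TRUE)
#' @param n_drop number of smallest eigenvalues to discard (default 6)
#' @param tol eigenvalue floor, amu Angstrom^2
#' @return list with `S_int` (kcal/mol/K), `omegas` (rad/s, ascending)
#'   and `lambdas` (amu Angstrom^2, the retained eigenvalues).
#' @export
quasiharmonic_internal_entropy <- function(trajectory, masses = NULL,
                                           temperature, fit = TRUE,
                                           n_drop = 6L, tol = 1e-8) {
  if (inherits(trajectory, "pt_trajectory")) {
    masses <- masses %||% atomic_masses(trajectory$topology)
    frames <- trajectory$frames
  } else frames <- trajectory
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  if (nf < n) warning("fewer frames (", nf, ") than atoms (", n,
                      "): covariance is rank-deficient")
  if (fit) {
    ref <- frames[, , 1]
    fitted <- array(0, dim = dim(frames))
    for (f in seq_len(nf))
      fitted[, , f] <- apply_transform(frames[, , f],
                                       superpose(frames[, , f], ref))
    # refit to the mean once so fluctuations are about the mean structure
    mean_xyz <- apply(fitted, c(1, 2), mean)
    for (f in seq_len(nf))
      fitted[, , f] <- apply_transform(frames[, , f],
                                       superpose(frames[, , f], mean_xyz))
    frames <- fitted
  }
  X <- t(matrix(frames, nrow = 3 * n))   # nf x 3n, (x1..xN, y1..yN, z1..zN)
  w <- rep(sqrt(masses), 3)
  Xw <- sweep(X, 2, colMeans(X)) * rep(w, each = nf)
  C <- crossprod(Xw) / nf
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  if (n_drop > 0 && length(ev) > n_drop)
    ev <- ev[-seq_len(n_drop)]
  ev <- ev[ev > tol]
  if (!length(ev))
    return(list(S_int = 0, omegas = numeric(0), lambdas = numeric(0)))
  cst <- pt_constants
  ev <- sort(ev, decreasing = TRUE)   # stiffest mode last after inversion
  omegas <- sqrt(cst$kB * temperature / (ev * cst$amu * 1e-20))
  list(S_int = sum(harmonic_mode_entropy(ev, temperature)),
       omegas = omegas, lambdas = ev)
}

#' Block-averaged solute entropy
#'
#' Splits the trajectory into `n_blocks` contiguous equal blocks (any
#' trailing remainder dropped), computes S = S_trans + S_rot + S_int per
#' block, and reports the mean and population SD across blocks.
#'
#' @param trajectory a `pt_trajectory`
#' @param n_blocks number of blocks (default 5, >= 2)
#' @param temperature K
#' @param V translational standard-state volume, L/mol
#' @param sigma rotational symmetry number
#' @param ... further arguments to [quasiharmonic_internal_entropy()]
#' @return list with `mean`, `sd` (kcal/mol/K) and the per-block
#'   component table `blocks`.
#' @export
block_entropy <- function(trajectory, n_blocks = 5L, temperature,
                          V = 1, sigma = 1, ...) {
  if (n_blocks < 2L) stop("need at least 2 blocks")
  nf <- n_frames(trajectory)
  per <- nf %/% n_blocks
  if (per < 2L) stop("too few frames for ", n_blocks, " blocks")
  masses <- atomic_masses(trajectory$topology)
  M <- sum(masses)
  s_tr <- translational_entropy(M, V, temperature)
  rows <- lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * per + 1L):(b * per)
    sub <- trajectory$frames[, , idx, drop = FALSE]
    mean_xyz <- apply(sub, c(1, 2), mean)
    I <- moments_of_inertia(mean_xyz, masses)
    s_rot <- rotational_entropy(I[1], I[2], I[3], temperature, sigma)
    s_int <- quasiharmonic_internal_entropy(sub, masses, temperature,
                                            ...)$S_int
    c(S_trans = s_tr, S_rot = s_rot, S_int = s_int,
      S = s_tr + s_rot + s_int)
  })
  blocks <- do.call(rbind, rows)
  s <- blocks[, "S"]
  list(mean = mean(s), sd = sqrt(mean((s - mean(s))^2)), blocks = blocks)
}

#' Assemble the thermodynamic-cycle free-energy shift
#'
#' Delta G = Delta E_conf + Delta Delta mu - T Delta S for one system's
#' pressure change, with SDs propagated in quadrature.
#'
#' @param delta_E_conf,delta_delta_mu,T_delta_S kcal/mol (each may be a
#'   `c(mean, sd)` vector; a bare number is taken as mean with SD 0)
#' @return list of class `pt_free_energy`: the three components plus
#'   `delta_G = c(mean, sd)`.
#' @export
free_energy_shift <- function(delta_E_conf, delta_delta_mu, T_delta_S) {
  as_ms <- function(x, nm) {
    if (is.null(x) || anyNA(x)) stop("missing component: ", nm)
    if (length(x) == 1L) c(mean = unname(x), sd = 0)
    else c(mean = unname(x[1]), sd = unname(x[2]))
  }
  e <- as_ms(delta_E_conf, "delta_E_conf")
  m <- as_ms(delta_delta_mu, "delta_delta_mu")
  ts <- as_ms(T_delta_S, "T_delta_S")
  dg <- c(mean = unname(e["mean"] + m["mean"] - ts["mean"]),
          sd = unname(sqrt(e["sd"]^2 + m["sd"]^2 + ts["sd"]^2)))
  structure(list(delta_E_conf = e, delta_delta_mu = m, T_delta_S = ts,
                 delta_G = dg), class = "pt_free_energy")
}

#' Free-energy breakdown table with a reference label
#'
#' Applies [free_energy_shift()] row-wise and reports Delta Delta G
#' relative to the reference system (zero for the reference itself).
#'
#' @param components data.frame with columns `label`, `delta_E_conf`,
#'   `delta_delta_mu`, `T_delta_S` and optional `sd_E`, `sd_mu`, `sd_TS`
#' @param reference_label label whose Delta G anchors Delta Delta G
#' @return data.frame with `delta_G`, `sd_G` and `delta_delta_G` added.
#' @export
free_energy_table <- function(components, reference_label) {
  need <- c("label", "delta_E_conf", "delta_delta_mu", "T_delta_S")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing component: ", paste(miss, collapse = ", "))
  if (!reference_label %in% components$label)
    stop("reference label ", reference_label, " not in table")
  out <- components
  col0 <- function(nm, i) if (is.null(out[[nm]])) 0 else out[[nm]][i]
  res <- lapply(seq_len(nrow(out)), function(i) {
    free_energy_shift(
      c(out$delta_E_conf[i], col0("sd_E", i)),
      c(out$delta_delta_mu[i], col0("sd_mu", i)),
      c(out$T_delta_S[i], col0("sd_TS", i)))
  })
  out$delta_G <- vapply(res, function(r) r$delta_G["mean"], numeric(1))
  out$sd_G <- vapply(res, function(r) r$delta_G["sd"], numeric(1))
  ref <- out$delta_G[out$label == reference_label][1]
  out$delta_delta_G <- out$delta_G - ref
  out
}
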