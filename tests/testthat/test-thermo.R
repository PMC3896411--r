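test_that("conformational-energy statistics and differences", {
  same <- mean_conformational_energy(rep(10, 50))
  expect_equal(unname(stat_difference(same$total, same$total)["mean"]), 0)
  dN <- c(mean = 100, sd = 3); dH <- c(mean = -47, sd = 4)
  d <- stat_difference(dN, dH)
  expect_equal(unname(d["mean"]), -147)
  expect_equal(unname(d["sd"]), 5)

  set.seed(111)
  x <- rnorm(4000, -120, 6)
  st <- mean_conformational_energy(
    data.frame(total = x, electrostatic = x / 2))
  sem <- 6 / sqrt(4000)
  expect_lt(abs(st$total["mean"] - (-120)), 3 * sem)
  expect_lt(abs(st$electrostatic["mean"] - (-60)), 3 * sem / 2)
})

test_that("nonbonded evaluator reproduces Coulomb arithmetic", {
  two <- quick_structure(c("A", "B"), c("X", "X"), "ION", 1:2,
                         rbind(c(0, 0, 0), c(3.32, 0, 0)))
  two$atoms$charge <- c(1, -1)
  e <- nonbonded_energy(two)
  expect_equal(e, -332.0637133 / 3.32, tolerance = 0.005)
  expect_lt(abs(e - (-100)) / 100, 0.005)

  one <- pt_structure(two$atoms[1, ])
  expect_equal(nonbonded_energy(one), 0)

  three <- quick_structure(c("A", "B", "C"), "X", "ION", 1:3,
                           rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  three$atoms$charge <- c(1, -1, 0.5)
  hand <- 332.0637133 * (-1 / 3 + 0.5 / 4 - 0.5 / 5)
  expect_equal(nonbonded_energy(three), hand, tolerance = 1e-9)
  three$atoms$charge[2] <- NA
  expect_error(nonbonded_energy(three), "unparameterized")
})

test_that("water dielectric is calibrated and monotone", {
  expect_equal(water_dielectric(298.15, 0.1), 78.4, tolerance = 0.02)
  expect_gt(water_dielectric(277, 60), water_dielectric(277, 0.1))
  expect_gt(water_dielectric(277, 0.1), water_dielectric(298.15, 0.1))
  expect_gt(water_dielectric(298.15, 0.1), water_dielectric(330, 0.1))
  expect_error(water_dielectric(250, 0.1), "range")
  expect_error(water_dielectric(298, 300), "range")
})

test_that("Poisson solver reproduces the Born closed form", {
  b <- gen_born_system(1, 2, 80)
  pol <- polar_solvation(b$structure, eps_in = 1, eps_out = 80,
                         radii = b$radii, grid_spacing = 0.4)
  expect_equal(pol, b$truth, tolerance = 0.05)
  expect_equal(pol, -81.9, tolerance = 0.05)

  zero <- gen_born_system(0, 2, 80)
  expect_equal(polar_solvation(zero$structure, radii = zero$radii), 0)

  b2 <- gen_born_system(2, 2, 80)
  pol2 <- polar_solvation(b2$structure, eps_in = 1, eps_out = 80,
                          radii = b2$radii, grid_spacing = 0.4)
  expect_equal(pol2, 4 * pol, tolerance = 0.01)
})

test_that("nonpolar solvation is gamma times area with zero vdW term", {
  expect_equal(nonpolar_solvation(0)$nonpolar, 0)
  np <- nonpolar_solvation(1e4, 277)
  expect_equal(np$nonpolar, 1091)
  expect_equal(np$vdw_term, 0)
  expect_equal(gamma_surface_tension(277), 0.1091)
  expect_error(nonpolar_solvation(-1), "negative")
})

test_that("translational entropy follows Sackur-Tetrode exactly", {
  s_ar <- translational_entropy(39.948, 24.8, 298)
  expect_equal(s_ar, 0.0370, tolerance = 0.01)
  kB_kcal <- pt_constants$R_kcal
  s1 <- translational_entropy(1000, 1, 277)
  expect_equal(translational_entropy(1000, 2, 277) - s1,
               kB_kcal * log(2), tolerance = 1e-12)
  expect_equal(translational_entropy(4000, 1, 277) - s1,
               1.5 * kB_kcal * log(4), tolerance = 1e-12)
  expect_error(translational_entropy(-1, 1, 277), "positive")
})

test_that("rotational entropy obeys its scaling laws and inertia oracle", {
  kB_kcal <- pt_constants$R_kcal
  s1 <- rotational_entropy(1e5, 2e5, 3e5, 277)
  expect_equal(rotational_entropy(8e5, 16e5, 24e5, 277) - s1,
               1.5 * kB_kcal * log(8), tolerance = 1e-12)
  expect_equal(rotational_entropy(1e5, 2e5, 3e5, 277, sigma = 2) - s1,
               -kB_kcal * log(2), tolerance = 1e-12)

  xyz <- rbind(c(1, 0, 0), c(-1, 0.2, 0), c(0, 1.5, 0.5), c(0, -1, -0.6))
  m <- c(12, 16, 14, 1)
  I <- moments_of_inertia(xyz, m)
  # brute-force inertia tensor
  com <- colSums(xyz * m) / sum(m)
  d <- sweep(xyz, 2, com)
  Imat <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    Imat[a, b] <- sum(m * ((a == b) * rowSums(d^2) - d[, a] * d[, b]))
  expect_equal(I, sort(eigen(Imat)$values), tolerance = 1e-10)
  expect_gt(rotational_entropy(I[1], I[2], I[3], 277), 0)
})

test_that("quasi-harmonic entropy recovers generator modes", {
  set.seed(112)
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  lam <- exp(runif(30, log(0.02), log(0.4)))
  g <- gen_harmonic_trajectory(ref, 2e4, temperature = 277,
                               mode_variances = lam, seed = 51)
  est <- quasiharmonic_internal_entropy(g$trajectory, temperature = 277,
                                        fit = FALSE, n_drop = 0)
  expect_equal(est$S_int, g$S_int_truth,
               tolerance = 0.02)
  expect_false(is.unsorted(est$omegas))
  expect_lte(length(est$omegas), 60)

  # stiffening every mode (lambda/4) lowers the entropy
  g4 <- gen_harmonic_trajectory(ref, 5000, temperature = 277,
                                mode_variances = lam / 4, seed = 52)
  e4 <- quasiharmonic_internal_entropy(g4$trajectory, temperature = 277,
                                       fit = FALSE, n_drop = 0)
  e1 <- quasiharmonic_internal_entropy(
    gen_harmonic_trajectory(ref, 5000, temperature = 277,
                            mode_variances = lam, seed = 52)$trajectory,
    temperature = 277, fit = FALSE, n_drop = 0)
  expect_lt(e4$S_int, e1$S_int)

  # coordinates with zero variance contribute no modes
  expect_lte(length(e1$lambdas), 30)

  # per-frame rigid rotations are removed by the fitting path
  gr <- gen_harmonic_trajectory(ref, 4000, temperature = 277,
                                mode_variances = lam[1:10],
                                rotate = TRUE, seed = 53)
  er <- quasiharmonic_internal_entropy(gr$trajectory, temperature = 277)
  expect_equal(er$S_int, gr$S_int_truth,
               tolerance = 0.10)
})

test_that("block entropy averages five contiguous blocks", {
  ref <- matrix(rnorm(36, sd = 4), 12, 3)
  g <- gen_harmonic_trajectory(ref, 1000, temperature = 277, sigma = 0.25,
                               seed = 54)
  be <- block_entropy(g$trajectory, n_blocks = 5, temperature = 277)
  expect_equal(nrow(be$blocks), 5L)
  expect_gt(be$mean, 0)

  # identical blocks give zero spread
  one <- g$trajectory$frames[, , 1:10]
  rep5 <- pt_trajectory(g$trajectory$topology,
                        array(rep(one, 5), dim = c(12, 3, 50)))
  be0 <- suppressWarnings(   # 10-frame blocks are rank-deficient, by design
    block_entropy(rep5, n_blocks = 5, temperature = 277))
  expect_equal(be0$sd, 0, tolerance = 1e-10)

  # block mean tracks the full-trajectory estimate
  full <- quasiharmonic_internal_entropy(g$trajectory,
                                         temperature = 277)$S_int
  masses <- atomic_masses(g$trajectory$topology)
  s_ext <- translational_entropy(sum(masses), 1, 277) +
    rotational_entropy(moments_of_inertia(ref, masses)[1],
                       moments_of_inertia(ref, masses)[2],
                       moments_of_inertia(ref, masses)[3], 277)
  expect_equal(be$mean, s_ext + full, tolerance = 0.03)
  expect_error(block_entropy(g$trajectory, n_blocks = 1,
                             temperature = 277), "blocks")
})

test_that("the thermodynamic cycle assembles and propagates SDs", {
  fe <- free_energy_shift(c(-147, 67), c(510, 22), c(29, 20))
  expect_equal(unname(fe$delta_G["mean"]), 334)
  expect_equal(unname(fe$delta_G["sd"]),
               sqrt(67^2 + 22^2 + 20^2), tolerance = 1e-12)
  expect_equal(unname(free_energy_shift(-153, 535, 30)$delta_G["mean"]),
               352)
  z <- free_energy_shift(0, 0, 0)
  expect_equal(unname(z$delta_G["mean"]), 0)
  expect_error(free_energy_shift(NA, 1, 1), "missing component")

  tab <- free_energy_table(
    data.frame(label = c("a", "b"), delta_E_conf = c(0, -10),
               delta_delta_mu = c(5, 5), T_delta_S = c(1, 1)),
    reference_label = "a")
  expect_equal(tab$delta_G, c(4, -6))
  expect_equal(tab$delta_delta_G, c(0, -10))
  expect_error(free_energy_table(
    data.frame(label = "a", delta_E_conf = 1, T_delta_S = 1), "a"),
    "missing component")
})
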