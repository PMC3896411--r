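test_that("superposition recovers rigid transforms and matches the
          quaternion oracle", {
  set.seed(101)
  X <- matrix(rnorm(150, sd = 3), 50, 3)
  s0 <- superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  Y <- X %*% t(Rz)
  s1 <- superpose(X, Y)
  expect_lt(s1$rmsd, 1e-8)
  expect_equal(s1$rotation, Rz, tolerance = 1e-8)

  Y2 <- X + matrix(rnorm(150, sd = 0.5), 50, 3)
  s2 <- superpose(X, Y2)
  o <- horn_superpose(X, Y2)
  expect_equal(s2$rmsd, o$rmsd, tolerance = 1e-6)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-8)

  expect_error(superpose(X[1:2, ], Y2[1:2, ]), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line + rnorm(15, sd = 1e-12), line), "collinear")
})

test_that("pairwise RMSD matrix is symmetric with n(n-1)/2 unique pairs", {
  set.seed(102)
  base <- matrix(rnorm(90, sd = 4), 30, 3)
  structs <- lapply(1:12, function(i)
    base + matrix(rnorm(90, sd = 0.3), 30, 3))
  m <- pairwise_rmsd_matrix(structs)
  expect_equal(dim(m), c(12L, 12L))
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 12), ignore_attr = TRUE)
  ut <- m[upper.tri(m)]
  expect_length(ut, 66L)           # 12 structures -> 66 combinations
  expect_true(all(ut > 0))
  for (k in 1:4) {
    i <- sample(12, 1); j <- sample(setdiff(1:12, i), 1)
    expect_equal(m[i, j], superpose(structs[[i]], structs[[j]])$rmsd,
                 tolerance = 1e-12)
  }
  expect_equal(max(pairwise_rmsd_matrix(list(base, base))), 0,
               tolerance = 1e-10)
})

test_that("iterative average structure converges to the generator mean", {
  ref <- matrix(rnorm(60, sd = 5), 20, 3)
  traj_same <- pt_trajectory(as_pseudo_structure(ref),
                             array(rep(ref, 3), dim = c(20, 3, 3)))
  avg <- average_structure(traj_same, selection = 1:20)
  expect_equal(coords(avg), ref, tolerance = 1e-8, ignore_attr = TRUE)

  # pure translation between two frames: the mean is equidistant
  tr2 <- pt_trajectory(as_pseudo_structure(ref),
                       array(c(ref, ref + 5), dim = c(20, 3, 2)))
  avg2 <- average_structure(tr2, selection = 1:20)
  r1 <- superpose(coords(avg2), ref)$rmsd
  r2 <- superpose(coords(avg2), ref + 5)$rmsd
  expect_equal(r1, r2, tolerance = 1e-6)

  sigma <- 0.3; nf <- 2000
  g <- gen_harmonic_trajectory(ref, nf, sigma = sigma, seed = 31)
  avg3 <- average_structure(g$trajectory, selection = 1:20)
  # after optimal alignment the mean should sit within sampling error
  expect_lt(superpose(coords(avg3), ref)$rmsd,
            3 * sigma * sqrt(3 / nf))
})

test_that("RMSF matches generator variances and rigid-body invariance", {
  ref <- matrix(rnorm(150, sd = 6), 50, 3)
  sigma <- 0.4
  g <- gen_harmonic_trajectory(ref, 3000, sigma = sigma, seed = 32)
  rf <- rmsf(g$trajectory, selection = 1:50, per_atom = TRUE)
  # best-fitting absorbs 6 of the 150 fluctuation dof
  expected <- sigma * sqrt(3) * sqrt(1 - 6 / 150)
  expect_equal(mean(rf), expected, tolerance = 0.05)

  # identical frames: zero everywhere
  t0 <- pt_trajectory(as_pseudo_structure(ref),
                      array(rep(ref, 4), dim = c(50, 3, 4)))
  expect_true(all(rmsf(t0, selection = 1:50, per_atom = TRUE) < 1e-10))

  # applying one rigid transform to every frame leaves RMSF unchanged
  R <- random_rotation_matrix()
  moved <- g$trajectory
  for (f in seq_len(n_frames(moved)))
    moved$frames[, , f] <- moved$frames[, , f] %*% t(R) + 3
  rf2 <- rmsf(moved, selection = 1:50, per_atom = TRUE)
  expect_equal(unname(rf2), unname(rf), tolerance = 1e-8)

  # a single atom oscillating +/- a in an otherwise rigid body
  a <- 0.5
  frames <- array(rep(ref, 200), dim = c(50, 3, 200))
  frames[1, 1, ] <- ref[1, 1] + a * rep(c(1, -1), 100)
  t1 <- pt_trajectory(as_pseudo_structure(ref), frames)
  rf3 <- rmsf(t1, selection = 1:50, per_atom = TRUE)
  # the best fit absorbs a sliver of the lone atom's motion
  expect_equal(unname(rf3[1]), a, tolerance = 0.07)
})

test_that("propeller angle follows the torsion convention and is
          rotation-invariant", {
  cent <- function(xyz) {
    n <- nrow(xyz)
    s <- as_pseudo_structure(xyz)
    sdm <- setNames(1:4, 1:4)
    propeller_angle(s, sdm, order = c(1, 2, 3, 4))
  }
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(cent(cis), 0, tolerance = 1e-9)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(cent(trans)), 180, tolerance = 1e-9)

  set.seed(103)
  for (rep in 1:5) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(cent(p),
                 torsion_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    R <- random_rotation_matrix()
    expect_equal(cent(sweep(p %*% t(R), 2, runif(3), "+")), cent(p),
                 tolerance = 1e-8)
  }
})

test_that("rotamer enumeration is the 3^n Cartesian product", {
  expect_equal(nrow(enumerate_rotamers("LYS")), 81L)
  expect_equal(nrow(enumerate_rotamers("SER")), 3L)
  expect_equal(nrow(enumerate_rotamers("GLN")), 27L)
  chi_types <- c("ARG", "LYS", "MET", "GLU", "GLN", "ASP", "ASN", "ILE",
                 "LEU", "HIS", "PHE", "TYR", "TRP", "PRO", "SER", "THR",
                 "VAL", "CYS")
  for (tp in chi_types)
    expect_equal(nrow(enumerate_rotamers(tp)), 3L^n_chi(tp))
  expect_warning(r <- enumerate_rotamers("GLY"), "no rotatable")
  expect_equal(nrow(r), 0L)
  # lexicographic ordering: first state all -60, last all 180
  rl <- enumerate_rotamers("LYS")
  expect_equal(unname(rl[1, ]), rep(-60, 4))
  expect_equal(unname(rl[81, ]), rep(180, 4))
})

test_that("rotamer selection maximises probe-anchor distance with
          deterministic ties", {
  mk_state <- function(chi, probe_pos) list(
    chi = chi, coords = matrix(probe_pos, 1, 3,
                               dimnames = list("NZ", NULL)))
  s5 <- mk_state(c(-60, -60, -60, -60), c(5, 0, 0))
  s7 <- mk_state(c(180, 180, 180, 180), c(7, 0, 0))
  got <- select_rotamer_max_distance(list(s5, s7), "NZ", c(0, 0, 0))
  expect_equal(got$distance, 7)

  tie <- select_rotamer_max_distance(list(s7, s5, mk_state(
    c(-60, 180, 60, 60), c(0, 7, 0))), "NZ", c(0, 0, 0))
  expect_equal(tie$chi, c(-60, 180, 60, 60))  # lexicographically first

  # all 81 lysine rotamers on a backbone stub vs exhaustive scan
  bb <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.0, 1.4, 0))
  anchor <- c(4, -2, 1)
  states <- apply(enumerate_rotamers("LYS"), 1, function(chi)
    list(chi = unname(chi), coords = build_sidechain(bb, "LYS", chi)),
    simplify = FALSE)
  got <- select_rotamer_max_distance(states, "NZ", anchor)
  dists <- vapply(states, function(s)
    sqrt(sum((s$coords["NZ", ] - anchor)^2)), numeric(1))
  expect_equal(got$distance, max(dists), tolerance = 1e-12)
  expect_equal(got$chi, states[[which.max(dists)]]$chi)
})

test_that("dihedral histograms are normalised and conserve mass", {
  bb <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.0, 1.4, 0))
  mk_frame <- function(chi1) {
    sc <- build_sidechain(bb, "LYS", c(chi1, 180, 180, 180))
    rbind(do.call(rbind, bb), sc)
  }
  topo <- quick_structure(
    c("N", "CA", "C", rownames(mk_frame(0))[-(1:3)]),
    c("N", "C", "C", "C", "C", "C", "C", "N"),
    "LYS", 1L, mk_frame(0))

  const <- pt_trajectory(topo, array(rep(mk_frame(-60), 50),
                                     dim = c(8, 3, 50)))
  h <- dihedral_histogram(const, 1, 1)
  expect_equal(sum(h$chi1$density * 5), 1, tolerance = 1e-9)
  occupied <- which(h$chi1$counts > 0)
  expect_length(occupied, 1L)
  expect_equal(h$chi1$density[occupied], 1 / 5)

  # evenly spaced angles across the full circle fill every bin equally,
  # including the wrap at +/-180
  chis <- seq(-180 + 0.125, 180, by = 0.25)
  frames <- array(0, dim = c(8, 3, length(chis)))
  for (i in seq_along(chis)) frames[, , i] <- mk_frame(chis[i])
  unif <- pt_trajectory(topo, frames)
  hu <- dihedral_histogram(unif, 1, 1)
  expect_equal(sum(hu$chi1$counts), length(chis))   # no mass lost
  expect_lt(max(hu$chi1$counts) / min(hu$chi1$counts), 1.3)
  expect_equal(sum(hu$chi1$density * 5), 1, tolerance = 1e-9)
})

test_that("minimum side-chain distances match brute force", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(1.5, -1.5, 0),
               c(0 + 5.4, 0, 0), c(1.5 + 5.4, 0, 0), c(2 + 5.4, 1.4, 0),
               c(1.5 + 5.4, -1.5, 0))
  s <- quick_structure(rep(c("N", "CA", "C", "CB"), 2),
                       rep(c("N", "C", "C", "C"), 2),
                       "ALA", rep(1:2, each = 4), xyz)
  tr <- pt_trajectory(s, array(xyz, dim = c(8, 3, 1)))
  cs <- min_sidechain_distance(tr, 1, 2)
  expect_equal(cs$mean, 5.4)       # CB-CB by construction
  expect_equal(cs$sd, 0)

  set.seed(104)
  frames <- array(rep(xyz, 5), dim = c(8, 3, 5)) +
    array(rnorm(8 * 3 * 5, sd = 0.3), dim = c(8, 3, 5))
  trn <- pt_trajectory(s, frames)
  cs2 <- min_sidechain_distance(trn, 1, 2)
  brute <- vapply(1:5, function(f)
    sqrt(sum((frames[4, , f] - frames[8, , f])^2)), numeric(1))
  expect_equal(cs2$values, brute, tolerance = 1e-12)

  expect_error(min_sidechain_distance(trn, 1, 2, element_filter = "S"),
               "no side-chain atoms")
})
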