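test_that("phi/psi windows assign canonical helix and strand", {
  h <- assign_secondary_structure(build_peptide(12, -57, -47))
  expect_equal(unname(h$labels[2:11]), rep("H", 10))
  e <- assign_secondary_structure(build_peptide(8, -120, 130))
  expect_equal(unname(e$labels[2:7]), rep("E", 6))
  # a 2-residue extended fragment stays coil (below run length)
  s2 <- assign_secondary_structure(build_peptide(2, -120, 130))
  expect_equal(unname(s2$labels), c("C", "C"))
  # contiguous runs share an element id, separated runs differ
  expect_length(unique(h$element_id[2:11]), 1L)
  ext <- assign_secondary_structure(
    build_peptide(20, c(rep(-57, 10), rep(-120, 10)),
                  c(rep(-47, 10), rep(130, 10))))
  ids <- unique(na.omit(ext$element_id))
  expect_gte(length(ids), 2L)
  # external annotation takes precedence
  lab <- setNames(rep("E", 12), 1:12)
  expect_equal(unname(assign_secondary_structure(
    build_peptide(12, -57, -47), external = lab)$labels), rep("E", 12))
})

test_that("salt-bridge detection is boundary-inclusive and exhaustive", {
  mk <- function(d) {
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0), c(d, 0, 2.2))
    quick_structure(c("NZ", "OD1", "OD2"), c("N", "O", "O"),
                    c("LYS", "ASP", "ASP"), c(1, 2, 2), xyz)
  }
  cfg <- list(subdomain_ranges = list(`1` = 1:2),
              nterm_charged = FALSE, cterm_charged = FALSE)
  anno <- annotate_topology(mk(3.2), cfg)
  expect_equal(nrow(detect_salt_bridges(mk(3.2), anno, 3.2)), 1L)
  expect_equal(nrow(detect_salt_bridges(mk(3.3), anno, 3.2)), 0L)

  # Arg (2 N-eta + N-eps) against 2 carboxylate oxygens: 6 records
  xyz <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(0.5, 0.9, 0),
               c(0.5, -2.0, 0), c(0.5, -2.0, 1.2))
  arg <- quick_structure(c("NH1", "NH2", "NE", "OD1", "OD2"),
                         c("N", "N", "N", "O", "O"),
                         c("ARG", "ARG", "ARG", "ASP", "ASP"),
                         c(1, 1, 1, 2, 2), xyz)
  anno2 <- annotate_topology(arg, cfg)
  rec <- detect_salt_bridges(arg, anno2, 3.2)
  # brute-force oracle over every (N, O) pair
  brute <- 0L
  for (i in 1:3) for (j in 4:5)
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 3.2) brute <- brute + 1L
  expect_equal(brute, 6L)
  expect_equal(nrow(rec), brute)

  # count is monotone non-increasing as the cutoff decreases
  cuts <- seq(3.4, 1.0, by = -0.4)
  ns <- vapply(cuts, function(cc)
    nrow(detect_salt_bridges(arg, anno2, cc)), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  w1 <- gen_water_molecule(c(0, 0, 0), c(1, 0, 0), resid = 901,
                           point_h1 = TRUE)
  w2 <- gen_water_molecule(c(2.8, 0, 0), c(0, 0, 1), resid = 902,
                           serial0 = 9100)
  dimer <- pt_structure(rbind(w1, w2))
  hb <- detect_hbonds(dimer, annotate_topology(dimer, list()))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  expect_equal(hb$category, "water_water")

  # bend the donor: same O-O distance, D-H...A angle of ~120
  w1b <- gen_water_molecule(c(0, 0, 0), c(cos(pi / 3), sin(pi / 3), 0),
                            resid = 901, point_h1 = TRUE)
  bent <- pt_structure(rbind(w1b, w2))
  hb2 <- detect_hbonds(bent, annotate_topology(bent, list()))
  expect_equal(nrow(hb2), 0L)

  # five-molecule cluster vs brute-force enumeration with the same rule
  set.seed(109)
  ows <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(0, 2.9, 0), c(-2.7, 0.3, 0),
               c(0.3, -2.8, 0.4))
  mols <- do.call(rbind, lapply(seq_len(nrow(ows)), function(i)
    gen_water_molecule(ows[i, ],
                       if (i == 1) c(1, 0, 0) else c(0, 0, 1),
                       resid = 900 + i, serial0 = 9000 + 10 * i,
                       point_h1 = (i == 1))))
  clus <- pt_structure(mols)
  hb3 <- detect_hbonds(clus, annotate_topology(clus, list()))
  xyz <- coords(clus); at <- clus$atoms
  brute <- 0L
  for (h in which(at$element == "H")) {
    d <- which(at$element == "O" &
                 sqrt(rowSums(sweep(xyz[, , drop = FALSE], 2,
                                    xyz[h, ])^2)) <= 1.25 &
                 at$resid == at$resid[h])[1]
    for (acc in which(at$element == "O")) {
      if (at$resid[acc] == at$resid[d]) next
      if (sqrt(sum((xyz[d, ] - xyz[acc, ])^2)) > 3.0) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= 160) brute <- brute + 1L
    }
  }
  expect_equal(nrow(hb3), brute)
})

test_that("classification combines secondary structure, subdomains and
          ATP tags", {
  residues <- data.frame(
    resname = c("LYS", "ASP", "LYS", "GLU"),
    resid = c(5, 8, 60, 90),
    ss = c("H", "H", "H", "E"),
    element_id = c(1, 1, 2, 3),
    subdomain = c(1, 1, 1, 3))
  fx <- gen_interaction_fixture(
    residues,
    pairs = data.frame(pos_resid = c(5, 60), neg_resid = c(8, 90),
                       distance = c(3.0, 3.1)))
  anno <- annotate_topology(fx$trajectory$topology, fx$config)
  rec <- classify_salt_bridges(
    detect_salt_bridges(frame_structure(fx$trajectory, 1), anno, 3.2),
    fx$ss_profile, fx$subdomains)
  r1 <- rec[rec$pos_resid == 5, ]
  expect_equal(r1$ss_category, "intra_helix_strand")
  expect_equal(r1$subdomain_category, "intra")
  r2 <- rec[rec$pos_resid == 60, ]
  expect_equal(r2$ss_category, "inter_helix_strand")
  expect_equal(r2$subdomain_category, "inter")

  # a K137 analogue contacting a gamma-oxygen of ATP
  fk <- gen_interaction_fixture(
    data.frame(resname = "LYS", resid = 137, ss = "C",
               element_id = NA, subdomain = 1),
    atp = list(pos_resid = 137, tag = "gamma", distance = 3.0))
  annok <- annotate_topology(fk$trajectory$topology, fk$config)
  reck <- classify_salt_bridges(
    detect_salt_bridges(frame_structure(fk$trajectory, 1), annok, 3.2),
    fk$ss_profile, fk$subdomains)
  expect_equal(nrow(reck), 1L)
  expect_equal(reck$atp_tag, "K137-O_gamma")
  expect_true(is.na(reck$ss_category))
})

test_that("aggregation reports mean/SD, both totals and formation rates", {
  fake <- function(n_ss, n_atp) {
    k <- n_ss + n_atp
    data.frame(pos_resid = seq_len(k), neg_resid = seq_len(k) + 100,
               ss_category = c(rep("inter_helix_strand", n_ss),
                               rep(NA, n_atp)),
               subdomain_category = c(rep("inter", n_ss), rep(NA, n_atp)),
               atp_tag = c(rep("none", n_ss), rep("other-ATP", n_atp)))
  }
  agg <- aggregate_interactions(list(fake(3, 0), fake(5, 0)))
  expect_equal(unname(agg$total["mean"]), 4)
  expect_equal(unname(agg$total["sd"]), 1)

  # a pair present in 7 of 10 frames has formation rate 0.7
  residues <- data.frame(resname = c("LYS", "ASP"), resid = c(1, 2),
                         ss = c("C", "C"), element_id = NA,
                         subdomain = c(1, 1))
  fx <- gen_interaction_fixture(
    residues,
    pairs = data.frame(pos_resid = 1, neg_resid = 2, distance = 3.0,
                       frames = I(list(1:7))),
    n_frames = 10)
  anno <- annotate_topology(fx$trajectory$topology, fx$config)
  per <- lapply(1:10, function(f) classify_salt_bridges(
    detect_salt_bridges(frame_structure(fx$trajectory, f), anno, 3.2),
    fx$ss_profile, fx$subdomains))
  agg2 <- aggregate_interactions(per)
  expect_equal(agg2$pair_rates$rate[agg2$pair_rates$pair == "1:2"], 0.7)
  expect_equal(fx$truth$formation_rates[["1:2"]], 0.7)
})

test_that("detection is invariant under rigid motion and atom order", {
  residues <- data.frame(resname = c("LYS", "ASP", "ARG", "GLU"),
                         resid = c(1, 2, 3, 4), ss = "C",
                         element_id = NA, subdomain = 1)
  fx <- gen_interaction_fixture(
    residues,
    pairs = data.frame(pos_resid = c(1, 3), neg_resid = c(2, 4),
                       distance = c(3.0, 2.9)))
  s <- frame_structure(fx$trajectory, 1)
  anno <- annotate_topology(s, fx$config)
  n0 <- nrow(detect_salt_bridges(s, anno, 3.2))
  set.seed(110)
  R <- random_rotation_matrix()
  sm <- set_coords(s, sweep(coords(s) %*% t(R), 2, runif(3, -9, 9), "+"))
  expect_equal(nrow(detect_salt_bridges(sm, anno, 3.2)), n0)
  perm <- sample(nrow(s$atoms))
  sp <- pt_structure(s$atoms[perm, ])
  annop <- annotate_topology(sp, fx$config)
  expect_equal(nrow(detect_salt_bridges(sp, annop, 3.2)), n0)
})
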