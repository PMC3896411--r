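# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Horn quaternion method for least-squares superposition: an eigenvalue
# route independent of the package's SVD implementation.
horn_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  S <- crossprod(P, Q)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fit <- sweep(P %*% t(R), 2, cr, "+")
  list(rotation = R, rmsd = sqrt(mean(rowSums((fit - reference)^2))))
}

# Torsion angle from explicit plane normals (vector-algebra oracle).
torsion_oracle <- function(p1, p2, p3, p4) {
  v1 <- p2 - p1; v2 <- p3 - p2; v3 <- p4 - p3
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- xp(v1, v2); n2 <- xp(v2, v3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(xp(n1, n2) * v2) < 0) ang <- -ang
  ang
}

# Closed-form accessible area of two intersecting inflated spheres.
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Closed-form union volume of two intersecting spheres.
two_sphere_volume <- function(R1, R2, d) {
  v <- 4 / 3 * pi * (R1^3 + R2^3)
  if (d >= R1 + R2) return(v)
  if (d <= abs(R1 - R2)) return(4 / 3 * pi * max(R1, R2)^3)
  lens <- pi * (R1 + R2 - d)^2 *
    (d^2 + 2 * d * R2 - 3 * R2^2 + 2 * d * R1 + 6 * R1 * R2 - 3 * R1^2) /
    (12 * d)
  v - lens
}

# Two-atom carbon structure at a given center separation.
two_atom_structure <- function(d, radius_class = "C_sp3") {
  s <- pt_structure(data.frame(
    serial = 1:2, name = "CA", element = "C", resname = "ALA",
    resid = 1:2, chain = "A", x = c(0, d), y = 0, z = 0))
  s$atoms$radius_class <- radius_class
  s
}

# Structure from a bare atom table with sensible defaults filled in.
quick_structure <- function(name, element, resname, resid, xyz,
                            chain = "A") {
  pt_structure(data.frame(
    serial = seq_along(name), name = name, element = element,
    resname = resname, resid = resid, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

ref_table <- function(name) {
  read.delim(system.file("extdata", name, package = "presstraj"))
}
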