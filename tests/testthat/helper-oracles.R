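# Independent oracles and shared fixtures for the test suite.

# Horn's quaternion method for optimal superposition RMSD: an eigenvalue
# solution fully independent of the SVD-based implementation under test.
quaternion_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R <- sweep(reference, 2, colMeans(reference))
  n <- nrow(M)
  Sxx <- sum(M[, 1] * R[, 1]); Sxy <- sum(M[, 1] * R[, 2])
  Sxz <- sum(M[, 1] * R[, 3])
  Syx <- sum(M[, 2] * R[, 1]); Syy <- sum(M[, 2] * R[, 2])
  Syz <- sum(M[, 2] * R[, 3])
  Szx <- sum(M[, 3] * R[, 1]); Szy <- sum(M[, 3] * R[, 2])
  Szz <- sum(M[, 3] * R[, 3])
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(M^2) + sum(R^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# second, independently derived torsion formula: signed angle between the
# projections of the outer bonds onto the plane perpendicular to the central
# bond
projection_torsion <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  e <- b2 / sqrt(sum(b2^2))
  u <- b1 - sum(b1 * e) * e
  v <- b3 - sum(b3 * e) * e
  cross <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(cross * e), sum(u * v)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 360)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  t <- th * pi / 180
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
  list(R = R, t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% t(tr$R), 2, tr$t, "+")
}

# a small U residue atom table from the generator, reused by conformation
# and screen tests
test_u_residue <- function(P = 18, nu_max = 38, chi = -158) {
  bh <- build_hairpin(hairpin_spec(
    stem_seq = "GG", loop_seq = "UUCAAAG",
    pucker = data.frame(position = 3, P = P, nu_max = nu_max),
    chi = data.frame(position = 3, chi = chi)))
  m <- bh$entry$models[[1]]
  m[urimod:::residue_gidx(m) == 3, ]
}

# cached toy corpus shared between the pipeline and acceptance tests
.test_cache <- new.env(parent = emptyenv())
get_toy_survey <- function() {
  if (is.null(.test_cache$survey)) {
    dir <- file.path(tempdir(), "urimod-toy-corpus")
    manifest <- generate_dataset(dir, seed = 1)
    result <- run_pipeline(manifest$modified_dir, manifest$library_dir)
    .test_cache$survey <- list(manifest = manifest, result = result,
                               dir = dir)
  }
  .test_cache$survey
}

two_atom_model <- function(d) {
  # an isolated donor (U N3) and acceptor (A N1) at separation d
  data.frame(chain = "A", seq = 1:2, icode = "", comp = c("U", "A"),
             atom = c("N3", "N1"), element = "N", alt = "", occ = 1,
             x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
}

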