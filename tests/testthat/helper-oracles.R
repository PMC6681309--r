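# Independent oracles used across tests.

# Brute-force Mann-Whitney: enumerate every split of the pooled sample and
# compute U by pairwise comparison counts (a different route than the
# package's midrank-sum enumeration).
brute_force_mw_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); m <- length(y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U_obs <- u_of(x, y)
  splits <- utils::combn(n + m, n)
  Us <- apply(splits, 2, function(ix) u_of(pool[ix], pool[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
}

# Shoelace polygon area.
shoelace <- function(v) {
  n <- nrow(v); j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Analytic annulus fraction by exact pixel counting against the circle
# equations on a pixel-centre grid (oracle for the rasterized pipeline).
pixel_count_annulus_fraction <- function(R, r, spacing, center = c(0, 0)) {
  half <- R + 2 * spacing
  n <- 2L * ceiling(half / spacing)
  u <- (seq_len(n) - 1 - (n - 1) / 2) * spacing
  rho2 <- outer((u - center[1])^2, (u - center[2])^2, "+")
  sum(rho2 <= R^2 & rho2 > r^2) / sum(rho2 <= R^2)
}

# A random rotation matrix (proper, det +1) from a seeded draw.
random_rotation <- function() {
  a <- stats::rnorm(3)
  a <- a / sqrt(sum(a^2))
  th <- stats::runif(1, 0.1, pi / 2)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# A generic (non-axis-aligned) valid landmark set.
random_landmark_set <- function() {
  rot <- random_rotation()
  shift <- stats::rnorm(3, 0, 5)
  transform_landmarks(
    landmark_set(nasal_bone_tip = c(-2.5, 0, 0),
                 atlas_anterior_arch = c(2.5, 0, 0),
                 nasal_bone_mid = c(0, 0, stats::runif(1, 1, 4)),
                 incisor_root = c(-2.5, 0, 0.3),
                 sagittal_suture = c(2.5, 0, 0.3),
                 frontoparietal_joint = c(0, 0, stats::runif(1, 1, 2)),
                 sagittal_normal = c(0, 1, 0)),
    rotation = rot, translation = shift)
}
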