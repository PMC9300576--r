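# Shared geometric fixtures, all built in code.

# Expected RANSAC trial counts computed once with 60-digit
# arbitrary-precision arithmetic (ceil(log(1-P)/log(1-rho^K))) and frozen.
trial_oracle <- local({
  g <- expand.grid(K = c(3L, 4L),
                   rho = seq(0.2, 0.9, by = 0.1),
                   P = c(0.9, 0.99, 0.999))
  g$S <- c(
    287L, 1438L, 85L, 284L, 35L, 89L, 18L, 36L, 10L, 17L, 6L, 9L,
    4L, 5L, 2L, 3L,
    574L, 2876L, 169L, 567L, 70L, 178L, 35L, 72L, 19L, 34L, 11L, 17L,
    7L, 9L, 4L, 5L,
    861L, 4314L, 253L, 850L, 105L, 267L, 52L, 108L, 29L, 50L, 17L, 26L,
    10L, 14L, 6L, 7L
  )
  g
})

# Rotation matrix about an axis (Rodrigues).
rot3 <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) * cos(angle) + sin(angle) * K +
    (1 - cos(angle)) * outer(axis, axis)
}

rigid_transform <- function(pts, R, t = c(0, 0, 0)) {
  sweep(as.matrix(pts) %*% t(R), 2, t, `+`)
}

rigid_cloud <- function(cloud, R, t = c(0, 0, 0)) {
  labeled_cloud(rigid_transform(cloud[, c("x", "y", "z")], R, t), cloud$label)
}

# Regular cylinder surface grid: n_rings rings of k evenly spaced points,
# axis along z from z = 0 down to z = -len. Exactly symmetric, so ring and
# slab centroids lie exactly on the axis.
cylinder_grid <- function(n_rings = 50, k = 20, radius = 10, len = 100) {
  s <- (seq_len(n_rings) - 0.5) / n_rings
  phi <- 2 * pi * (seq_len(k) - 1) / k
  g <- expand.grid(s = s, phi = phi)
  cbind(radius * cos(g$phi), radius * sin(g$phi), -len * g$s)
}

# Points on a circle in 2D, optionally noisy (seeded by the caller).
circle_points2d <- function(n, center = c(0, 0), radius = 1, sigma = 0) {
  phi <- runif(n, 0, 2 * pi)
  r <- radius + rnorm(n, sd = sigma)
  cbind(center[1] + r * cos(phi), center[2] + r * sin(phi))
}

# Random points exactly on a sphere surface.
sphere_points <- function(n, center = c(0, 0, 0), radius = 1) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(1 - z^2)
  sweep(cbind(rho * cos(phi), rho * sin(phi), z) * radius, 2, center, `+`)
}

cross_for_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Normalized axial coordinate of points under a shaft parameterization,
# recomputed independently of the package internals.
shaft_fraction_for_test <- function(pts, param) {
  (drop(as.matrix(pts) %*% param$axis_dir) - param$t_min) / param$length
}

# Independent confusion-matrix computation for Dice / IoU oracles.
brute_confusion <- function(pred, truth, num_classes) {
  sapply(0:(num_classes - 1), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    c(tp = tp, fp = fp, fn = fn)
  })
}
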