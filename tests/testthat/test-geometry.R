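test_that("least-squares sphere fit recovers exact spheres", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  s <- fit_sphere_lsq(octa)
  expect_equal(s$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(s$radius, 1, tolerance = 1e-12)

  s2 <- fit_sphere_lsq(sweep(octa, 2, c(10, 20, 30), `+`))
  expect_equal(s2$center, c(10, 20, 30), tolerance = 1e-9)
  expect_equal(s2$radius, 1, tolerance = 1e-9)

  set.seed(11)
  pts <- sphere_points(25, center = c(-4, 7, 2.5), radius = 17)
  s3 <- fit_sphere_lsq(pts)
  expect_lt(sqrt(sum((s3$center - c(-4, 7, 2.5))^2)), 1e-9)
  expect_lt(abs(s3$radius - 17), 1e-9)
})

test_that("sphere fit is rotation- and translation-equivariant", {
  set.seed(21)
  pts <- sphere_points(60, center = c(2, -1, 5), radius = 30)
  base <- fit_sphere_lsq(pts)
  for (i in 1:5) {
    R <- rot3(rnorm(3), runif(1, 0, pi))
    t <- rnorm(3, sd = 50)
    s <- fit_sphere_lsq(rigid_transform(pts, R, t))
    expect_lt(sqrt(sum((s$center - (drop(R %*% base$center) + t))^2)), 1e-9)
    expect_lt(abs(s$radius - base$radius), 1e-9)
  }
})

test_that("noisy sphere fit agrees with an iterative geometric refit", {
  set.seed(5)
  truth_c <- c(5, -3, 2)
  pts <- sphere_points(2048, center = truth_c, radius = 22) +
    matrix(rnorm(2048 * 3, sd = 0.5), ncol = 3)
  fit <- fit_sphere_lsq(pts)
  # oracle: geometric least squares (minimize sum (|p - c| - R)^2), started
  # at the true centre, profiled over R
  geo_obj <- function(cc) {
    d <- sqrt(rowSums(sweep(pts, 2, cc)^2))
    sum((d - mean(d))^2)
  }
  geo <- optim(truth_c, geo_obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_lt(sqrt(sum((fit$center - geo$par)^2)), 0.05)
})

test_that("sphere fit rejects degenerate inputs", {
  expect_error(fit_sphere_lsq(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               class = "nsafit_degenerate")
  coplanar <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_error(fit_sphere_lsq(coplanar), class = "nsafit_degenerate")
})

test_that("centroid is the arithmetic mean and is rigid-equivariant", {
  expect_equal(
    centroid3(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))),
    c(0.5, 0.5, 0.5)
  )
  expect_equal(centroid3(rbind(c(3, -1, 7))), c(3, -1, 7))
  set.seed(31)
  pts <- matrix(rnorm(60), ncol = 3)
  R <- rot3(c(1, 1, 0), 0.7)
  expect_equal(centroid3(rigid_transform(pts, R, c(1, 2, 3))),
               drop(R %*% centroid3(pts)) + c(1, 2, 3), tolerance = 1e-12)
  expect_error(centroid3(matrix(numeric(0), ncol = 3)),
               class = "nsafit_validation")
})

test_that("plane construction contains its points and has a unit normal", {
  p <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(p$C), 1)
  expect_equal(p$A, 0)
  expect_equal(p$D, 0)
  set.seed(41)
  for (i in 1:10) {
    tri <- matrix(rnorm(9, sd = 20), ncol = 3)
    pl <- plane_from_points(tri[1, ], tri[2, ], tri[3, ])
    expect_equal(sum(pl$normal^2), 1, tolerance = 1e-12)
    for (j in 1:3) {
      expect_lt(abs(sum(pl$normal * tri[j, ]) + pl$D), 1e-9)
    }
  }
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "nsafit_degenerate")
})

test_that("point-to-plane projection is the foot of the perpendicular", {
  pz <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(project_point(pz, c(1, 1, 1)), c(1, 1, 0))
  # plane x + y + z = 3: origin projects to (1,1,1) (t = -1)
  pd <- plane_from_points(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  expect_equal(project_point(pd, c(0, 0, 0)), c(1, 1, 1), tolerance = 1e-12)
  # idempotence and minimal distance
  set.seed(51)
  for (i in 1:5) {
    p <- rnorm(3, sd = 10)
    proj <- project_point(pd, p)
    expect_equal(project_point(pd, proj), proj, tolerance = 1e-9)
    for (j in 1:10) {
      q <- project_point(pd, rnorm(3, sd = 10))
      expect_lte(sqrt(sum((p - proj)^2)), sqrt(sum((p - q)^2)) + 1e-12)
    }
  }
})

test_that("projection commutes with centroids (affinity)", {
  set.seed(61)
  pl <- plane_from_points(rnorm(3), rnorm(3) + 5, rnorm(3) - 5)
  pts <- matrix(rnorm(90, sd = 15), ncol = 3)
  expect_equal(project_point(pl, centroid3(pts)),
               centroid3(project_point(pl, pts)), tolerance = 1e-9)
})

test_that("plane basis is orthonormal and round-trips 2D coordinates", {
  set.seed(71)
  for (i in 1:8) {
    pl <- plane_from_points(rnorm(3, sd = 5), rnorm(3, sd = 5), rnorm(3, sd = 5))
    origin <- project_point(pl, rnorm(3, sd = 5))
    b <- plane_basis(pl, origin)
    expect_lt(abs(sum(b$e1 * b$e2)), 1e-12)
    expect_lt(abs(sum(b$e1 * pl$normal)), 1e-12)
    expect_lt(abs(sum(b$e2 * pl$normal)), 1e-12)
    expect_equal(sum(b$e1^2), 1, tolerance = 1e-12)
    pts <- project_point(pl, matrix(rnorm(30, sd = 10), ncol = 3))
    expect_equal(from_plane_2d(b, to_plane_2d(b, pts)), pts, tolerance = 1e-9)
  }
  pz <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  bz <- plane_basis(pz, c(0, 0, 0))
  expect_equal(abs(bz$e1[3]), 0, tolerance = 1e-12)
  expect_equal(abs(bz$e2[3]), 0, tolerance = 1e-12)
  expect_error(plane_basis(pz, c(0, 0, 1)), class = "nsafit_validation")
})

test_that("vector angle matches closed forms and its symmetries", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 1, 0), c(1, 0, 0)), 45, tolerance = 1e-12)
  set.seed(81)
  for (i in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(angle_between(u, v), angle_between(v, u))
    expect_equal(angle_between(u, -v), 180 - angle_between(u, v),
                 tolerance = 1e-9)
  }
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)),
               class = "nsafit_degenerate")
})

test_that("inverse-distance weighting interpolates and hits exact matches", {
  expect_equal(
    idw_interpolate(c(0, 0, 0), rbind(c(-1, 0, 0), c(1, 0, 0)), c(0, 1)),
    0.5
  )
  expect_equal(
    idw_interpolate(c(2, 0, 0), rbind(c(1, 1, 1), c(2, 0, 0)), c(3, 7)),
    7
  )
  # p = 2, k = 2, distances 1 and 2 to values 0 and 3: (0 + 0.25 * 3) / 1.25
  expect_equal(
    idw_interpolate(c(0, 0, 0), rbind(c(1, 0, 0), c(0, 2, 0)), c(0, 3),
                    power = 2, k = 2),
    0.6
  )
  # symmetric neighbours reproduce affine functions exactly
  set.seed(91)
  a <- rnorm(3); b <- rnorm(1)
  f <- function(p) sum(a * p) + b
  q <- rnorm(3)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  nb <- sweep(offs, 2, q, `+`)
  # equidistant pairs get equal weight, so their affine values average to f(q)
  expect_equal(
    idw_interpolate(q, nb, apply(nb, 1, f), power = 2, k = 4),
    f(q), tolerance = 1e-12
  )
  expect_error(idw_interpolate(c(0, 0, 0), matrix(numeric(0), ncol = 3),
                               numeric(0)),
               class = "nsafit_validation")
})
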