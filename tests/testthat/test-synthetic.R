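test_that("the generator is deterministic and matches its analytic truth", {
  sp <- femur_spec(nsa_true = 132, anteversion = 10, seed = 77)
  a <- generate_femur(sp)
  b <- generate_femur(sp)
  expect_identical(as.data.frame(a$cloud), as.data.frame(b$cloud))
  expect_identical(a$truth$head_center, b$truth$head_center)
  # ground-truth angle is exact by construction
  expect_equal(
    angle_between(a$truth$neck_axis$direction, a$truth$shaft_axis$direction),
    132, tolerance = 1e-9
  )
  expect_equal(a$truth$nsa_true, 132)
  # all three regions populated, n_points total
  expect_equal(nrow(a$cloud), 2048)
  expect_true(all(table(a$cloud$label) > 100))
})

test_that("the ground-truth axes are exactly the requested distance apart", {
  for (off in c(0, 2, 5, 10)) {
    tr <- generate_femur(femur_spec(axis_offset = off, seed = 1))$truth
    n <- cross_for_test(tr$neck_axis$direction, tr$shaft_axis$direction)
    gap <- abs(sum(n / sqrt(sum(n^2)) *
                     (tr$shaft_axis$anchor - tr$neck_axis$anchor)))
    expect_equal(gap, off, tolerance = 1e-9)
    expect_equal(
      angle_between(tr$neck_axis$direction, tr$shaft_axis$direction),
      126, tolerance = 1e-9
    )
  }
})

test_that("invalid specifications are rejected", {
  expect_error(femur_spec(nsa_true = 60), class = "nsafit_spec")
  expect_error(femur_spec(nsa_true = 185), class = "nsafit_spec")
  expect_error(femur_spec(head_radius = -1), class = "nsafit_spec")
  expect_error(femur_spec(outlier_fraction = 0.6), class = "nsafit_spec")
  expect_error(femur_spec(n_points = 100), class = "nsafit_spec")
  expect_error(femur_spec(neck_length = 20, head_radius = 22),
               class = "nsafit_spec")
})

test_that("emitted labels agree with nearest-primitive classification", {
  sp <- femur_spec(noise_sigma = 0, seed = 33)
  fem <- generate_femur(sp)
  tr <- fem$truth
  pts <- as.matrix(fem$cloud[, c("x", "y", "z")])
  # distance to each generating surface, computed independently
  d_sphere <- abs(sqrt(rowSums(sweep(pts, 2, tr$head_center)^2)) -
                    sp$head_radius)
  frustum_dist <- function(pts, base, dir, len, r0, r1) {
    rel <- sweep(pts, 2, base)
    t <- drop(rel %*% dir)
    tc <- pmin(pmax(t, 0), len)
    rad <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
    r_at <- r0 + (r1 - r0) * tc / len
    sqrt((t - tc)^2 + (rad - r_at)^2)
  }
  d_neck <- frustum_dist(pts, tr$neck_base, tr$neck_axis$direction,
                         sp$neck_length, sp$neck_radius,
                         0.75 * sp$neck_radius)
  s <- pmin(pmax(-pts[, 3] / sp$shaft_length, 0), 1)
  d_shaft <- abs(sqrt(pts[, 1]^2 +
                        (pts[, 2] - sp$shaft_bow * sin(pi * s))^2) -
                   sp$shaft_radius) + ifelse(-pts[, 3] < 0 |
                                               -pts[, 3] > sp$shaft_length,
                                             abs(s * sp$shaft_length + pts[, 3]),
                                             0)
  nearest <- max.col(-cbind(d_sphere, d_neck, d_shaft)) - 1L
  expect_gte(mean(nearest == fem$cloud$label), 0.999)
})

test_that("noise-free offset-free femurs are recovered without bias", {
  errs <- sapply(1:8, function(sd) {
    fem <- generate_femur(femur_spec(noise_sigma = 0, axis_offset = 0,
                                     shaft_bow = 0, seed = sd))
    measure_nsa_3d(fem$cloud)$nsa_deg - 126
  })
  expect_lt(max(abs(errs)), 0.5)
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("outlier contamination is bounded and labels are retained", {
  sp <- femur_spec(outlier_fraction = 0.2, seed = 55)
  fem <- generate_femur(sp)
  clean <- generate_femur(femur_spec(outlier_fraction = 0, seed = 55))
  expect_identical(fem$cloud$label, clean$cloud$label)
  moved <- rowSums(abs(as.matrix(fem$cloud[, 1:3]) -
                         as.matrix(clean$cloud[, 1:3]))) > 0
  expect_equal(sum(moved), round(0.2 * 2048))
})

test_that("sweeps tabulate both methods against the truth", {
  specs <- lapply(1:4, function(i) femur_spec(nsa_true = 118 + 4 * i, seed = i))
  sw <- sweep_femurs(specs)
  expect_s3_class(sw, "nsa_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(is.na(sw$error)))
  expect_equal(sw$err_3d, abs(sw$nsa_3d - sw$nsa_true))
  g <- glance(sw)
  expect_equal(g$n_ok, 4L)
  expect_true(all(is.finite(c(g$mean_err_3d_deg, g$accuracy_2d_3d_pct))))
  expect_s3_class(autoplot(sw), "ggplot")
  expect_error(sweep_femurs(list()), class = "nsafit_validation")
})
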