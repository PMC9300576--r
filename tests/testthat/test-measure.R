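test_that("neck and shaft axes follow the anatomical orientation convention", {
  na <- neck_axis_3d(c(0, 0, 10), c(0, 0, 0))
  expect_equal(na$direction, c(0, 0, 1))
  expect_equal(na$anchor, c(0, 0, 0))
  na2 <- neck_axis_3d(c(0, 0, 0), c(0, 0, 10))
  expect_equal(na2$direction, -na$direction)
  expect_error(neck_axis_3d(c(1, 1, 1), c(1, 1, 1)),
               class = "nsafit_degenerate")

  sa <- shaft_axis_3d(c(0, 0, 100), c(0, 0, 80))
  expect_equal(sa$direction, c(0, 0, -1))
  expect_error(shaft_axis_3d(c(1, 2, 3), c(1, 2, 3)),
               class = "nsafit_degenerate")
  R <- rot3(c(1, 0, 1), 0.9)
  sa2 <- shaft_axis_3d(drop(R %*% c(0, 0, 100)), drop(R %*% c(0, 0, 80)))
  expect_equal(sa2$direction, drop(R %*% c(0, 0, -1)), tolerance = 1e-12)
})

test_that("3D measurement recovers the true angle on clean synthetic femurs", {
  fem <- generate_femur(femur_spec(noise_sigma = 0, axis_offset = 0, seed = 2))
  r <- measure_nsa_3d(fem$cloud)
  expect_lt(abs(r$nsa_deg - 126), 0.5)
  expect_identical(r$method, "3d")
  expect_null(r$plane)
  expect_true(all(c("head_center", "neck", "shaft_slab_60_70",
                    "shaft_slab_70_80", "shaft_distal10") %in%
                    names(r$centroids)))
  # neck direction against the generator's analytic axis
  expect_lt(
    angle_between(r$neck_axis$direction, fem$truth$neck_axis$direction), 0.5
  )
})

test_that("missing regions are reported by name", {
  fem <- generate_femur(femur_spec(seed = 3))
  no_neck <- fem$cloud[fem$cloud$label != 1, ]
  expect_error(measure_nsa_3d(no_neck), regexp = "neck",
               class = "nsafit_validation")
})

test_that("an introduced axis offset appears as the closest-approach diagnostic", {
  fem <- generate_femur(femur_spec(axis_offset = 5, noise_sigma = 0,
                                   shaft_bow = 0, seed = 8))
  # the generator's analytic axes are exactly 5 mm apart at closest approach
  tr <- fem$truth
  n <- cross_for_test(tr$neck_axis$direction, tr$shaft_axis$direction)
  gap <- abs(sum(n / sqrt(sum(n^2)) *
                   (tr$shaft_axis$anchor - tr$neck_axis$anchor)))
  expect_equal(gap, 5, tolerance = 1e-9)
  r <- measure_nsa_3d(fem$cloud)
  expect_equal(r$diagnostics$closest_approach_mm, 5, tolerance = 0.05)
  # and the measured angle is unaffected by the offset (directions only)
  expect_lt(abs(r$nsa_deg - 126), 0.5)
})

test_that("projection plane passes through the three anatomical centroids", {
  fem <- generate_femur(femur_spec(noise_sigma = 0, anteversion = 0,
                                   axis_offset = 0, shaft_bow = 0, seed = 5))
  bp <- build_projection_plane(fem$cloud)
  pl <- bp$plane
  for (nm in c("head_center", "neck", "shaft_distal10")) {
    expect_lt(abs(sum(pl$normal * bp$centroids[[nm]]) + pl$D), 1e-9)
  }
  # planar femur: the generator's axis-defining points lie on the plane
  for (p in list(fem$truth$head_center, fem$truth$neck_base, c(0, 0, 0))) {
    expect_lt(abs(sum(pl$normal * p) + pl$D), 1e-6)
  }
})

test_that("anteverted femur axes stay close to the simulated radiograph plane", {
  fem <- generate_femur(femur_spec(anteversion = 15, noise_sigma = 0, seed = 9))
  bp <- build_projection_plane(fem$cloud)
  ang_to_plane <- function(d) abs(90 - angle_between(d, bp$plane$normal))
  expect_lt(ang_to_plane(fem$truth$neck_axis$direction), 3)
  expect_lt(ang_to_plane(fem$truth$shaft_axis$direction), 3)
})

test_that("a straight-line phantom defeats the plane construction", {
  # all three centroids on the z-axis by symmetric construction
  head <- sweep(rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0), c(0, -10, 0),
                      c(0, 0, 10), c(0, 0, -10)), 2, c(0, 0, 100), `+`)
  phi <- 2 * pi * (0:7) / 8
  neck <- cbind(5 * cos(phi), 5 * sin(phi), 70)
  shaft <- cylinder_grid(20, 12, radius = 8, len = 50)
  cl <- labeled_cloud(rbind(head, neck, shaft),
                      rep(0:2, c(nrow(head), nrow(neck), nrow(shaft))))
  expect_error(build_projection_plane(cl), class = "nsafit_degenerate")
})

test_that("2D measurement agrees with 3D on a planar femur and carries its plane", {
  fem <- generate_femur(femur_spec(noise_sigma = 0, anteversion = 0,
                                   axis_offset = 0, shaft_bow = 0, seed = 4))
  r3 <- measure_nsa_3d(fem$cloud)
  r2 <- measure_nsa_2d(fem$cloud, ransac_config(seed = 4))
  expect_lt(abs(r2$nsa_deg - r3$nsa_deg), 0.1)
  expect_identical(r2$method, "2d")
  expect_s3_class(r2$plane, "plane")
  expect_lt(abs(sum(r2$neck_axis$direction * r2$plane$normal)), 1e-9)
  expect_lt(abs(sum(r2$shaft_axis$direction * r2$plane$normal)), 1e-9)
})

test_that("noisy 2D measurement stays close to the generator truth", {
  errs <- sapply(1:5, function(sd) {
    fem <- generate_femur(femur_spec(seed = sd))
    abs(measure_nsa_2d(fem$cloud, ransac_config(seed = sd))$nsa_deg - 126)
  })
  expect_lt(mean(errs), 2.5)
})

test_that("the 2D shaft axis is the projection of the 3D shaft axis", {
  fem <- generate_femur(femur_spec(seed = 10))
  r3 <- measure_nsa_3d(fem$cloud)
  r2 <- measure_nsa_2d(fem$cloud, ransac_config(seed = 10))
  proj_dir <- project_point(r2$plane, r3$shaft_axis$anchor +
                              r3$shaft_axis$direction) -
    project_point(r2$plane, r3$shaft_axis$anchor)
  expect_lt(angle_between(proj_dir, r2$shaft_axis$direction), 1e-6)
})

test_that("measured angles land near the truth, never near the supplement", {
  for (nsa in c(110, 126, 150)) {
    fem <- generate_femur(femur_spec(nsa_true = nsa, seed = 20 + nsa))
    r3 <- measure_nsa_3d(fem$cloud)
    r2 <- measure_nsa_2d(fem$cloud, ransac_config(seed = 20 + nsa))
    expect_lt(abs(r3$nsa_deg - nsa), 5)
    expect_lt(abs(r2$nsa_deg - nsa), 5)
    expect_gt(abs(r3$nsa_deg - (180 - nsa)), 20)
  }
})

test_that("sub-90-degree results trigger the orientation guard", {
  ax1 <- neck_axis_3d(c(0, 0, 10), c(0, 0, 0))
  ax2 <- shaft_axis_3d(c(0, 0, 0), c(5, 0, -10))
  expect_warning(
    nsafit:::new_nsa_result("3d", 60, ax1, ax2, NULL, list(), list(), "x"),
    regexp = "orientation"
  )
  expect_error(
    nsafit:::new_nsa_result("3d", 181, ax1, ax2, NULL, list(), list(), "x"),
    class = "nsafit_degenerate"
  )
})

test_that("tidy and glance expose the axes and the headline angle", {
  fem <- generate_femur(femur_spec(seed = 15))
  r <- measure_nsa_3d(fem$cloud)
  td <- tidy(r)
  expect_identical(td$axis, c("neck", "shaft"))
  expect_equal(sqrt(td$dir_x^2 + td$dir_y^2 + td$dir_z^2), c(1, 1),
               tolerance = 1e-12)
  g <- glance(r)
  expect_identical(nrow(g), 1L)
  expect_equal(g$nsa_deg, r$nsa_deg)
  expect_identical(g$method, "3d")
})

test_that("autoplot returns a ggplot for both methods", {
  fem <- generate_femur(femur_spec(seed = 16))
  r3 <- measure_nsa_3d(fem$cloud)
  r2 <- measure_nsa_2d(fem$cloud, ransac_config(seed = 16))
  expect_s3_class(autoplot(r3, fem$cloud), "ggplot")
  expect_s3_class(autoplot(r2, fem$cloud), "ggplot")
})
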