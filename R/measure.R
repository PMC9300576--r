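new_axis <- function(anchor, direction) {
  structure(
    list(anchor = unname(anchor), direction = unitize(unname(direction))),
    class = "axis3"
  )
}

#' @export
print.axis3 <- function(x, ...) {
  cat(sprintf(
    "<axis3> anchor (%.3f, %.3f, %.3f), direction (%.4f, %.4f, %.4f)\n",
    x$anchor[1], x$anchor[2], x$anchor[3],
    x$direction[1], x$direction[2], x$direction[3]
  ))
  invisible(x)
}

#' Femoral neck axis from head centre and neck centroid
#'
#' The neck axis is the line connecting the fitted head-sphere centre with
#' the neck centroid, oriented neck-to-head so that the angle with the
#' proximal-to-distal shaft axis lands in the anatomical neck-shaft-angle
#' range (about 126 degrees) rather than its supplement.
#'
#' @param head_center,neck_centroid Length-3 points (mm), > 1e-6 mm apart.
#' @return An axis: list with `anchor` (the neck centroid) and unit
#'   `direction` (towards the head centre).
#' @export
neck_axis_3d <- function(head_center, neck_centroid) {
  d <- head_center - neck_centroid
  if (vnorm(d) <= 1e-6) {
    abort("head centre and neck centroid coincide", class = "nsafit_degenerate")
  }
  new_axis(neck_centroid, d)
}

#' Femoral shaft axis from two slab centroids
#'
#' The shaft axis is the line through the centroids of the 60-70% and 70-80%
#' axial slabs of the shaft, oriented proximal-to-distal. The slabs sit away
#' from the lesser trochanter (error-prone) and proximal to the bowed
#' mid-diaphysis.
#'
#' @param slab_60_70_centroid,slab_70_80_centroid Length-3 points (mm).
#' @return An axis anchored at the 60-70% centroid, pointing distally.
#' @export
shaft_axis_3d <- function(slab_60_70_centroid, slab_70_80_centroid) {
  d <- slab_70_80_centroid - slab_60_70_centroid
  if (vnorm(d) <= 1e-6) {
    abort("shaft slab centroids coincide", class = "nsafit_degenerate")
  }
  new_axis(slab_60_70_centroid, d)
}

# Shared per-cloud anatomy: head sphere, neck centroid, shaft parameterization
# and the slab/distal centroids both measurement routes are built from.
cloud_anatomy <- function(cloud, slabs = c(0.6, 0.7, 0.8), distal_frac = 0.10,
                          percent_base = c("shaft", "cloud")) {
  percent_base <- match.arg(percent_base)
  cloud <- labeled_cloud(cloud, id = cloud_id(cloud))
  head_pts <- region_points(cloud, 0L, "head")
  neck_pts <- region_points(cloud, 1L, "neck")
  shaft_pts <- region_points(cloud, 2L, "shaft")
  head_sphere <- fit_sphere_lsq(head_pts)
  neck_c <- centroid3(neck_pts)
  param <- shaft_param(shaft_pts, proximal_hint = head_sphere$center)
  if (percent_base == "cloud") {
    t_all <- drop(as_xyz_matrix(cloud) %*% param$axis_dir)
    param$t_min <- min(t_all)
    param$t_max <- max(t_all)
    param$length <- param$t_max - param$t_min
  }
  slab_a <- extract_slab(shaft_pts, param, slabs[1], slabs[2])
  slab_b <- extract_slab(shaft_pts, param, slabs[2], slabs[3])
  distal <- distal_fraction(shaft_pts, param, distal_frac)
  list(
    cloud = cloud, head_pts = head_pts, neck_pts = neck_pts,
    shaft_pts = shaft_pts, head_sphere = head_sphere, neck_centroid = neck_c,
    shaft_parameterization = param,
    slab_a = slab_a, slab_b = slab_b, distal = distal,
    centroids = list(
      head_center = head_sphere$center,
      neck = neck_c,
      shaft_slab_60_70 = centroid3(slab_a),
      shaft_slab_70_80 = centroid3(slab_b),
      shaft_distal10 = centroid3(distal)
    )
  )
}

new_nsa_result <- function(method, nsa_deg, neck_axis, shaft_axis, plane,
                           centroids, diagnostics, id) {
  if (!is.finite(nsa_deg) || nsa_deg <= 0 || nsa_deg >= 180) {
    abort("measured angle outside (0, 180) degrees", class = "nsafit_degenerate")
  }
  if (nsa_deg < 90) {
    warning(
      sprintf(
        "measured neck-shaft angle %.1f deg is below 90 deg; probable axis-orientation fault (supplement would be %.1f deg)",
        nsa_deg, 180 - nsa_deg
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      id = id, method = method, nsa_deg = nsa_deg,
      neck_axis = neck_axis, shaft_axis = shaft_axis,
      plane = plane, centroids = centroids, diagnostics = diagnostics
    ),
    class = "nsa_result"
  )
}

#' Measure the neck-shaft angle directly in 3D
#'
#' The 3D route: the femoral head is fitted with a least-squares sphere, the
#' neck centroid is taken over the neck-labeled points, the shaft is
#' parameterized along its principal axis, and the neck-shaft angle is the
#' vector angle between the neck axis (neck centroid to head centre) and the
#' shaft axis (60-70% to 70-80% slab centroids). Because the two fitted axes
#' are generally skew in space, their closest-approach distance is reported
#' as a diagnostic.
#'
#' @param cloud A [labeled_cloud()] (or data frame with `x,y,z,label`) with
#'   all three regions present.
#' @param slabs Three increasing fractions giving the two shaft slabs;
#'   default `c(0.6, 0.7, 0.8)`.
#' @param distal_frac Distal shaft fraction recorded among the centroids;
#'   default 0.10.
#' @param percent_base Whether slab percentages are measured over the labeled
#'   shaft only (`"shaft"`, default) or over the whole cloud's axial extent
#'   (`"cloud"`).
#' @return An object of class `"nsa_result"`; see [tidy.nsa_result()] and
#'   [glance.nsa_result()].
#' @examples
#' fem <- generate_femur(femur_spec(seed = 1))
#' measure_nsa_3d(fem$cloud)
#' @export
measure_nsa_3d <- function(cloud, slabs = c(0.6, 0.7, 0.8), distal_frac = 0.10,
                           percent_base = "shaft") {
  an <- cloud_anatomy(cloud, slabs, distal_frac, percent_base)
  neck_axis <- neck_axis_3d(an$centroids$head_center, an$centroids$neck)
  shaft_axis <- shaft_axis_3d(
    an$centroids$shaft_slab_60_70, an$centroids$shaft_slab_70_80
  )
  nsa <- angle_between(neck_axis$direction, shaft_axis$direction)
  new_nsa_result(
    method = "3d", nsa_deg = nsa,
    neck_axis = neck_axis, shaft_axis = shaft_axis, plane = NULL,
    centroids = an$centroids,
    diagnostics = list(
      closest_approach_mm = line_line_distance(
        neck_axis$anchor, neck_axis$direction,
        shaft_axis$anchor, shaft_axis$direction
      ),
      head_radius_mm = an$head_sphere$radius,
      shaft_length_mm = an$shaft_parameterization$length
    ),
    id = cloud_id(an$cloud)
  )
}

#' Build the simulated anteroposterior projection plane
#'
#' The plane through three anatomical points — the fitted head-sphere centre,
#' the neck centroid, and the centroid of the distal 10% of the shaft —
#' emulates the standard hip anteroposterior radiograph, in which internal
#' rotation of the limb counterbalances femoral anteversion so the neck lies
#' in the image plane.
#'
#' @inheritParams measure_nsa_3d
#' @return List with `plane` (a `"plane"`) and `centroids` (the three
#'   defining points plus slab centroids).
#' @export
build_projection_plane <- function(cloud, slabs = c(0.6, 0.7, 0.8),
                                   distal_frac = 0.10, percent_base = "shaft") {
  an <- cloud_anatomy(cloud, slabs, distal_frac, percent_base)
  plane <- plane_from_points(
    an$centroids$head_center, an$centroids$neck, an$centroids$shaft_distal10
  )
  list(plane = plane, centroids = an$centroids, anatomy = an)
}

#' Measure the neck-shaft angle on the projection plane
#'
#' The 2D route: the cloud is projected orthogonally onto the simulated
#' anteroposterior plane of [build_projection_plane()]; the projected head —
#' a disc whose rim is a circle concentric with the projected sphere centre —
#' is fitted by RANSAC circle consensus; the neck axis runs from that circle
#' centre to the projected neck centroid, the shaft axis through the
#' projected 60-70% and 70-80% slab centroids (slab membership computed in 3D
#' before projection; projection is affine so the projected-member centroids
#' equal the projections of the 3D centroids); the angle is the vector angle
#' of the two in-plane directions.
#'
#' @inheritParams measure_nsa_3d
#' @param config A [ransac_config()] controlling the projected-head circle
#'   fit.
#' @param boundary_only Fit the RANSAC circle only to the outer rim of the
#'   projected head (points beyond `boundary_quantile` of the radial spread
#'   about the projected-head centroid). Default `TRUE`: the projected solid
#'   head is a filled disc whose inner annuli are denser than the rim, so a
#'   consensus maximized over all points systematically prefers interior
#'   circles; the sphere centre is carried by the silhouette boundary.
#'   `FALSE` fits all projected head points.
#' @param boundary_quantile Radial quantile defining the rim when
#'   `boundary_only = TRUE`; default 0.7.
#' @return An object of class `"nsa_result"` carrying the projection plane.
#' @examples
#' fem <- generate_femur(femur_spec(seed = 1))
#' measure_nsa_2d(fem$cloud)
#' @export
measure_nsa_2d <- function(cloud, config = ransac_config(),
                           slabs = c(0.6, 0.7, 0.8), distal_frac = 0.10,
                           percent_base = "shaft",
                           boundary_only = TRUE, boundary_quantile = 0.7) {
  bp <- build_projection_plane(cloud, slabs, distal_frac, percent_base)
  an <- bp$anatomy
  plane <- bp$plane
  neck_c2 <- project_point(plane, an$centroids$neck)
  basis <- plane_basis(plane, neck_c2)

  head2d <- to_plane_2d(basis, project_point(plane, an$head_pts))
  fit_pts <- head2d
  if (isTRUE(boundary_only)) {
    ctr0 <- colMeans(head2d)
    r <- sqrt((head2d[, 1] - ctr0[1])^2 + (head2d[, 2] - ctr0[2])^2)
    fit_pts <- head2d[r >= stats::quantile(r, boundary_quantile), , drop = FALSE]
  }
  rans <- fit_circle_ransac(fit_pts, config)
  head_center2 <- from_plane_2d(basis, rans$circle$center)

  slab_a2 <- centroid3(project_point(plane, an$slab_a))
  slab_b2 <- centroid3(project_point(plane, an$slab_b))

  neck_axis <- neck_axis_3d(head_center2, neck_c2)
  shaft_axis <- shaft_axis_3d(slab_a2, slab_b2)
  nsa <- angle_between(neck_axis$direction, shaft_axis$direction)
  new_nsa_result(
    method = "2d", nsa_deg = nsa,
    neck_axis = neck_axis, shaft_axis = shaft_axis, plane = plane,
    centroids = an$centroids,
    diagnostics = list(
      projected_head_center = head_center2,
      head_circle_radius_mm = rans$circle$radius,
      ransac_inlier_ratio = rans$inlier_ratio,
      ransac_trials = rans$n_trials,
      head_radius_mm = an$head_sphere$radius,
      shaft_length_mm = an$shaft_parameterization$length
    ),
    id = cloud_id(an$cloud)
  )
}

#' @export
print.nsa_result <- function(x, ...) {
  cat(sprintf(
    "<nsa_result> '%s' (%s method): neck-shaft angle %.2f deg\n",
    x$id, x$method, x$nsa_deg
  ))
  if (x$method == "3d") {
    cat(sprintf(
      "  axis closest approach: %.2f mm (neck and shaft axes are generally skew)\n",
      x$diagnostics$closest_approach_mm
    ))
  } else {
    cat(sprintf(
      "  projection plane: %.3fx + %.3fy + %.3fz + %.3f = 0\n",
      x$plane$A, x$plane$B, x$plane$C, x$plane$D
    ))
  }
  invisible(x)
}

#' Tidy a neck-shaft-angle measurement
#'
#' `tidy()` returns one row per fitted axis (anchor and direction
#' components); `glance()` returns a one-row summary with the angle and
#' diagnostics.
#'
#' @param x An `"nsa_result"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nsa_result <- function(x, ...) {
  ax <- list(neck = x$neck_axis, shaft = x$shaft_axis)
  purrr::map2_dfr(ax, names(ax), function(a, nm) {
    tibble::tibble(
      axis = nm,
      anchor_x = a$anchor[1], anchor_y = a$anchor[2], anchor_z = a$anchor[3],
      dir_x = a$direction[1], dir_y = a$direction[2], dir_z = a$direction[3]
    )
  })
}

#' @rdname tidy.nsa_result
#' @export
glance.nsa_result <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    method = x$method,
    nsa_deg = x$nsa_deg,
    closest_approach_mm = x$diagnostics$closest_approach_mm %||% NA_real_,
    head_radius_mm = x$diagnostics$head_radius_mm %||% NA_real_,
    shaft_length_mm = x$diagnostics$shaft_length_mm %||% NA_real_
  )
}

#' Plot a neck-shaft-angle measurement
#'
#' Draws the cloud projected onto the measurement plane (the projection plane
#' for the 2D method; the plane spanned by the two fitted axes for the 3D
#' method), coloured by region, with the fitted neck and shaft axes overlaid.
#'
#' @param object An `"nsa_result"`.
#' @param cloud The measured [labeled_cloud()] (results do not retain the
#'   full cloud).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nsa_result <- function(object, cloud, ...) {
  cloud <- labeled_cloud(cloud, id = cloud_id(cloud))
  if (object$method == "2d") {
    plane <- object$plane
  } else {
    n <- cross3(object$neck_axis$direction, object$shaft_axis$direction)
    n <- unitize(n)
    plane <- new_plane(n[1], n[2], n[3], -sum(n * object$neck_axis$anchor))
  }
  origin <- project_point(plane, object$centroids$neck)
  basis <- plane_basis(plane, origin)
  p2 <- to_plane_2d(basis, project_point(plane, as_xyz_matrix(cloud)))
  df <- tibble::tibble(
    u = p2[, 1], v = p2[, 2],
    region = factor(cloud$label, 0:2, c("head", "neck", "shaft"))
  )
  axis_seg <- function(a, len_neg, len_pos, what) {
    p0 <- to_plane_2d(basis, project_point(plane, a$anchor - len_neg * a$direction))
    p1 <- to_plane_2d(basis, project_point(plane, a$anchor + len_pos * a$direction))
    tibble::tibble(u = p0[1], v = p0[2], uend = p1[1], vend = p1[2], axis = what)
  }
  head_r <- object$diagnostics$head_radius_mm %||% 25
  shaft_l <- object$diagnostics$shaft_length_mm %||% 150
  segs <- dplyr::bind_rows(
    axis_seg(object$neck_axis, 10, 2 * head_r, "neck axis"),
    axis_seg(object$shaft_axis, 0.65 * shaft_l, 0.3 * shaft_l, "shaft axis")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region),
                        size = 0.4, alpha = 0.6) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$u, y = .data$v, xend = .data$uend,
                   yend = .data$vend, linetype = .data$axis),
      colour = "black", linewidth = 0.6
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s: neck-shaft angle %.1f deg (%s method)",
                      object$id, object$nsa_deg, object$method),
      x = "in-plane u (mm)", y = "in-plane v (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Write and read measurement results as JSON
#'
#' `write_result()` serializes an `"nsa_result"` to a machine-parseable JSON
#' file (`id`, `method`, `nsa_deg`, both axes as anchor/direction, the
#' projection plane in unit-normal form or `null` for the 3D method, and all
#' region centroids); `read_result()` reads it back.
#'
#' @param result An `"nsa_result"`.
#' @param path Output (input) file path.
#' @return `write_result()`: `path`, invisibly. `read_result()`: an
#'   `"nsa_result"`.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "nsa_result"))
  obj <- list(
    id = result$id,
    method = result$method,
    nsa_deg = result$nsa_deg,
    neck_axis = list(anchor = result$neck_axis$anchor,
                     direction = result$neck_axis$direction),
    shaft_axis = list(anchor = result$shaft_axis$anchor,
                      direction = result$shaft_axis$direction),
    plane = if (is.null(result$plane)) NULL else
      list(A = result$plane$A, B = result$plane$B,
           C = result$plane$C, D = result$plane$D),
    centroids = result$centroids,
    diagnostics = result$diagnostics
  )
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
          class = "nsafit_io")
  }
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "nsafit_io")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane <- NULL
  if (!is.null(obj$plane) && length(obj$plane) > 0) {
    plane <- new_plane(obj$plane$A, obj$plane$B, obj$plane$C, obj$plane$D)
  }
  new_nsa_result(
    method = obj$method, nsa_deg = obj$nsa_deg,
    neck_axis = new_axis(obj$neck_axis$anchor, obj$neck_axis$direction),
    shaft_axis = new_axis(obj$shaft_axis$anchor, obj$shaft_axis$direction),
    plane = plane,
    centroids = obj$centroids,
    diagnostics = obj$diagnostics,
    id = obj$id
  )
}
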