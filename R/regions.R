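#' Parameterize the femoral shaft along its long axis
#'
#' Fits the dominant principal direction of the labeled shaft points and
#' orients it proximal-to-distal using a proximal landmark (normally the
#' fitted head-sphere centre). Scalar projections of the shaft points onto
#' this axis define the 0-100% axial coordinate that the percentage slabs
#' are cut from.
#'
#' @param shaft_points Data frame with `x,y,z` or n x 3 matrix of
#'   shaft-labeled points (>= 10 points spanning > 10 mm).
#' @param proximal_hint A 3D point on the proximal side (head centre or neck
#'   centroid); the axis is flipped to point away from it.
#' @return List of class `"shaft_param"`: `axis_point` (shaft centroid),
#'   `axis_dir` (unit, proximal to distal), `t_min`, `t_max`, `length` (mm).
#' @export
shaft_param <- function(shaft_points, proximal_hint) {
  pts <- as_xyz_matrix(shaft_points, "shaft_points")
  if (nrow(pts) < 10L) {
    abort("shaft parameterization needs >= 10 points", class = "nsafit_validation")
  }
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev
  if (sdev[1] <= 0 || (sdev[2] / sdev[1]) > 0.95) {
    abort(
      "shaft point set is near-isotropic; no dominant axis",
      class = "nsafit_degenerate"
    )
  }
  dir <- pc$rotation[, 1]
  # orient proximal -> distal: away from the proximal landmark
  if (sum(dir * (ctr - proximal_hint)) < 0) dir <- -dir
  t <- drop(pts %*% dir)
  t_min <- min(t)
  t_max <- max(t)
  if (t_max - t_min <= 10) {
    abort("shaft spans <= 10 mm along its axis", class = "nsafit_degenerate")
  }
  structure(
    list(
      axis_point = unname(ctr), axis_dir = unname(dir),
      t_min = t_min, t_max = t_max, length = t_max - t_min
    ),
    class = "shaft_param"
  )
}

#' @export
print.shaft_param <- function(x, ...) {
  cat(sprintf(
    "<shaft_param> length %.1f mm, axis (%.3f, %.3f, %.3f)\n",
    x$length, x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]
  ))
  invisible(x)
}

shaft_fraction <- function(points, param) {
  pts <- as_xyz_matrix(points)
  (drop(pts %*% param$axis_dir) - param$t_min) / param$length
}

#' Extract an axial slab of the shaft
#'
#' Returns the points whose normalized axial coordinate `s = (t - t_min) /
#' length` lies in `[lo, hi)`; the interval is half-open so adjacent slabs
#' partition the shaft without double counting, except that `hi = 1` also
#' includes the distal endpoint `s = 1`.
#'
#' @param points Data frame with `x,y,z` or n x 3 matrix (typically the shaft
#'   region).
#' @param param A [shaft_param()].
#' @param lo,hi Fractions with `0 <= lo < hi <= 1`.
#' @return n x 3 matrix of the slab members.
#' @export
extract_slab <- function(points, param, lo, hi) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    abort("need 0 <= lo < hi <= 1", class = "nsafit_validation")
  }
  pts <- as_xyz_matrix(points)
  s <- shaft_fraction(pts, param)
  keep <- s >= lo & (s < hi | (hi == 1 & s <= 1))
  if (!any(keep)) {
    abort(
      sprintf("empty shaft slab [%.2f, %.2f)", lo, hi),
      class = "nsafit_empty_region"
    )
  }
  pts[keep, , drop = FALSE]
}

#' Distal fraction of the shaft
#'
#' The slab `[1 - fraction, 1]` in the proximal-to-distal parameterization —
#' by default the distal 10% of the labeled shaft, the third anchor point of
#' the simulated anteroposterior projection plane.
#'
#' @inheritParams extract_slab
#' @param fraction Fraction of the shaft length, in (0, 1); default 0.10.
#' @return n x 3 matrix of the distal points.
#' @export
distal_fraction <- function(points, param, fraction = 0.10) {
  if (!(fraction > 0 && fraction < 1)) {
    abort("`fraction` must be in (0, 1)", class = "nsafit_validation")
  }
  extract_slab(points, param, 1 - fraction, 1)
}
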