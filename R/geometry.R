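#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points by the linear least-squares method: coordinates
#' are mean-centred, the 3x3 normal equations for the centre are solved
#' directly, and the radius is the root-mean-square distance of the points
#' from the fitted centre. This is the standard algebraic sphere fit used to
#' locate the femoral head centre from the segmented head region.
#'
#' @param points A data frame with columns `x`, `y`, `z`, or an n x 3 numeric
#'   matrix, in millimetres. At least 4 non-coplanar points are required.
#' @return An object of class `"sphere"`: a list with `center` (length-3
#'   numeric, mm) and `radius` (mm).
#' @examples
#' octa <- rbind(
#'   c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
#'   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
#' )
#' fit_sphere_lsq(octa)
#' @export
fit_sphere_lsq <- function(points) {
  pts <- as_xyz_matrix(points)
  if (nrow(pts) < 4L) {
    abort("sphere fit needs at least 4 points", class = "nsafit_degenerate")
  }
  ctr <- colMeans(pts)
  u <- sweep(pts, 2, ctr) # mean-centred coordinates
  M <- crossprod(u) # [Suu Suv Suw; ...]
  r2 <- rowSums(u^2)
  b <- colSums(u * r2) / 2
  cn <- tryCatch(kappa(M, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e12) {
    abort(
      "sphere fit is degenerate: points are (near-)coplanar",
      class = "nsafit_degenerate"
    )
  }
  c0 <- tryCatch(solve(M, b), error = function(e) {
    abort("sphere fit is degenerate: points are (near-)coplanar",
          class = "nsafit_degenerate")
  })
  center <- c0 + ctr
  radius <- sqrt(mean(rowSums(sweep(pts, 2, center)^2)))
  structure(
    list(center = unname(center), radius = radius),
    class = "sphere"
  )
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf(
    "<sphere> center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n",
    x$center[1], x$center[2], x$center[3], x$radius
  ))
  invisible(x)
}

#' Centroid of a point set
#'
#' Component-wise arithmetic mean of a set of 3D points — the estimator used
#' for the femoral neck and shaft-slab reference points, chosen because the
#' irregular neck surface makes the centroid more stable than any single
#' landmark.
#'
#' @inheritParams fit_sphere_lsq
#' @return Length-3 numeric (mm).
#' @export
centroid3 <- function(points) {
  pts <- as_xyz_matrix(points)
  if (nrow(pts) == 0L) {
    abort("centroid of an empty point set", class = "nsafit_validation")
  }
  unname(colMeans(pts))
}

#' Plane through three points
#'
#' Builds the implicit plane `A x + B y + C z + D = 0` through three
#' non-collinear points, with `(A, B, C)` normalized to a unit vector.
#'
#' @param p1,p2,p3 Length-3 numeric points (mm).
#' @return An object of class `"plane"`: list with fields `A`, `B`, `C`, `D`
#'   and `normal` (the unit vector `c(A, B, C)`).
#' @export
plane_from_points <- function(p1, p2, p3) {
  e1 <- p2 - p1
  e2 <- p3 - p1
  n <- cross3(e1, e2)
  scale <- vnorm(e1) * vnorm(e2)
  if (scale == 0 || vnorm(n) <= 1e-9 * scale) {
    abort(
      "the three points are (near-)collinear; no unique plane",
      class = "nsafit_degenerate"
    )
  }
  n <- unitize(n)
  new_plane(n[1], n[2], n[3], -sum(n * p1))
}

new_plane <- function(A, B, C, D) {
  n <- vnorm(c(A, B, C))
  structure(
    list(A = A / n, B = B / n, C = C / n, D = D / n,
         normal = c(A, B, C) / n),
    class = "plane"
  )
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf(
    "<plane> %.4fx + %.4fy + %.4fz + %.4f = 0\n", x$A, x$B, x$C, x$D
  ))
  invisible(x)
}

plane_signed_distance <- function(plane, points) {
  pts <- as_xyz_matrix(points)
  drop(pts %*% plane$normal) + plane$D
}

#' Orthogonal projection onto a plane
#'
#' Foot of the perpendicular from each point to the plane: with a unit normal
#' the parametric distance is `t = A x + B y + C z + D` and the projection is
#' `p - t * (A, B, C)`. Used to cast the segmented femur onto the simulated
#' anteroposterior radiograph plane.
#'
#' @param plane A `"plane"` object.
#' @param points A single length-3 point, a data frame with `x`,`y`,`z`, or an
#'   n x 3 matrix.
#' @return Projected points in the same shape as the input (a length-3 vector
#'   for a single point, otherwise an n x 3 matrix).
#' @export
project_point <- function(plane, points) {
  single <- is.numeric(points) && is.null(dim(points)) && length(points) == 3L
  pts <- if (single) matrix(points, 1L, 3L) else as_xyz_matrix(points)
  t <- drop(pts %*% plane$normal) + plane$D
  out <- pts - outer(t, plane$normal)
  if (single) drop(out) else out
}

#' Orthonormal in-plane basis
#'
#' Deterministic pair of orthonormal vectors spanning a plane, seeded from the
#' coordinate axis with the smallest-magnitude normal component; together with
#' an in-plane origin these give 2D coordinates for projected points.
#'
#' @param plane A `"plane"` object.
#' @param origin A point on the plane (within 1e-6 mm) used as the 2D origin.
#' @return List with unit vectors `e1`, `e2` and the `origin`.
#' @export
plane_basis <- function(plane, origin) {
  if (abs(sum(plane$normal * origin) + plane$D) > 1e-6) {
    abort("`origin` does not lie on the plane", class = "nsafit_validation")
  }
  seed_axis <- diag(3)[, which.min(abs(plane$normal))]
  e1 <- unitize(cross3(plane$normal, seed_axis))
  e2 <- cross3(plane$normal, e1)
  list(e1 = e1, e2 = e2, origin = origin)
}

#' Convert between 3D and in-plane 2D coordinates
#'
#' @param basis A basis from [plane_basis()].
#' @param points 3D points (for `to_plane_2d`) or 2D in-plane coordinates
#'   (for `from_plane_2d`).
#' @return `to_plane_2d`: n x 2 matrix of in-plane coordinates;
#'   `from_plane_2d`: n x 3 matrix of 3D points.
#' @export
to_plane_2d <- function(basis, points) {
  single <- is.numeric(points) && is.null(dim(points)) && length(points) == 3L
  pts <- if (single) matrix(points, 1L, 3L) else as_xyz_matrix(points)
  d <- sweep(pts, 2, basis$origin)
  out <- cbind(drop(d %*% basis$e1), drop(d %*% basis$e2))
  if (single) drop(out) else out
}

#' @rdname to_plane_2d
#' @export
from_plane_2d <- function(basis, points) {
  single <- is.numeric(points) && is.null(dim(points)) && length(points) == 2L
  pts <- if (single) matrix(points, 1L, 2L) else as.matrix(points)
  out <- outer(pts[, 1], basis$e1) + outer(pts[, 2], basis$e2)
  out <- sweep(out, 2, basis$origin, `+`)
  if (single) drop(out) else out
}

#' Angle between two directions
#'
#' The vector-angle formula: the arccosine of the dot product of the unit
#' directions, clamped to `[-1, 1]` against rounding, in degrees. This is the
#' formula evaluated on the fitted neck and shaft axis directions to give the
#' neck-shaft angle.
#'
#' @param u,v Length-3 direction vectors (normalized internally).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_between(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
angle_between <- function(u, v) {
  u <- unitize(u)
  v <- unitize(v)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Inverse-distance-weighted interpolation
#'
#' Propagates per-point values to a query location: the weighted mean of the
#' `k` nearest neighbours with weights `1 / d^power`, falling back to the
#' neighbour's own value when the query coincides with it (distance below
#' 1e-12 mm). This is the label/feature up-sampling rule used when dense
#' per-point predictions are interpolated from a sparse subset.
#'
#' @param query Length-3 numeric query point.
#' @param neighbors Data frame with `x`,`y`,`z` or n x 3 matrix of neighbour
#'   locations.
#' @param values Numeric vector or matrix (one row per neighbour) of values to
#'   interpolate.
#' @param power Positive distance exponent (default 2).
#' @param k Number of nearest neighbours used (default 3, capped at the
#'   neighbour count).
#' @return Interpolated value: numeric vector with one entry per value column.
#' @examples
#' idw_interpolate(c(0, 0, 0), rbind(c(-1, 0, 0), c(1, 0, 0)), c(0, 1))
#' @export
idw_interpolate <- function(query, neighbors, values, power = 2, k = 3L) {
  pts <- as_xyz_matrix(neighbors, "neighbors")
  vals <- if (is.null(dim(values))) matrix(values, ncol = 1L) else as.matrix(values)
  if (nrow(pts) == 0L) {
    abort("empty neighbour set", class = "nsafit_validation")
  }
  if (nrow(vals) != nrow(pts)) {
    abort("`values` must have one row per neighbour", class = "nsafit_validation")
  }
  if (power <= 0) abort("`power` must be positive", class = "nsafit_validation")
  d <- sqrt(rowSums(sweep(pts, 2, query)^2))
  hit <- which(d < 1e-12)
  if (length(hit) > 0L) {
    return(drop(vals[hit[1L], ]))
  }
  k <- min(as.integer(k), nrow(pts))
  sel <- order(d)[seq_len(k)]
  w <- 1 / d[sel]^power
  drop(colSums(vals[sel, , drop = FALSE] * w) / sum(w))
}

# Minimal distance between two lines (anchor + unit direction); the femoral
# neck and shaft axes are generally skew, and this closest-approach distance
# is reported as a diagnostic.
line_line_distance <- function(a1, d1, a2, d2) {
  n <- cross3(d1, d2)
  nn <- vnorm(n)
  if (nn < 1e-12) {
    # parallel: point-to-line distance
    w <- a2 - a1
    return(vnorm(w - sum(w * d1) * d1))
  }
  abs(sum(n / nn * (a2 - a1)))
}
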