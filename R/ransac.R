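#' RANSAC configuration
#'
#' Parameters for the robust circle fit of the projected femoral head.
#' `confidence` is the probability of drawing at least one all-inlier minimal
#' sample; `inlier_ratio_floor` is the most pessimistic inlier fraction
#' assumed before any consensus is observed (the adaptive schedule replaces
#' it with the best observed ratio); `inlier_threshold` is the absolute
#' point-to-circle distance (mm) below which a point counts as an inlier —
#' the default 1.0 mm is about 1.6x the 0.625 mm voxel pitch of the source
#' scans.
#'
#' @param confidence Probability in (0, 1); default 0.99.
#' @param inlier_ratio_floor Probability in (0, 1); default 0.2.
#' @param sample_size Minimal sample size (3 for a circle).
#' @param inlier_threshold Inlier distance threshold in mm; default 1.0.
#' @param max_trials Hard cap on hypothesis draws; default 1000.
#' @param seed Integer RNG seed making the fit reproducible; default 0.
#' @return A list of class `"ransac_config"`.
#' @export
ransac_config <- function(confidence = 0.99, inlier_ratio_floor = 0.2,
                          sample_size = 3L, inlier_threshold = 1.0,
                          max_trials = 1000L, seed = 0L) {
  stopifnot(
    confidence > 0, confidence < 1,
    inlier_ratio_floor > 0, inlier_ratio_floor < 1,
    sample_size >= 3L, inlier_threshold > 0, max_trials >= 1L
  )
  structure(
    list(
      confidence = confidence, inlier_ratio_floor = inlier_ratio_floor,
      sample_size = as.integer(sample_size),
      inlier_threshold = inlier_threshold,
      max_trials = as.integer(max_trials), seed = seed
    ),
    class = "ransac_config"
  )
}

#' Minimum number of RANSAC trials
#'
#' The classical trial-count bound: the smallest number of minimal-sample
#' draws S such that, with inlier fraction `inlier_ratio` and `sample_size`
#' points per draw, at least one all-inlier draw occurs with probability
#' `confidence`: `S = ceil(log(1 - P) / log(1 - rho^K))`.
#'
#' @param confidence P, in (0, 1).
#' @param inlier_ratio rho, in (0, 1].
#' @param sample_size K, number of points per minimal sample.
#' @return Integer trial count (1 when every point is an inlier).
#' @examples
#' ransac_trials(0.99, 0.5, 3) # 35
#' @export
ransac_trials <- function(confidence, inlier_ratio, sample_size) {
  stopifnot(confidence > 0, confidence < 1,
            inlier_ratio > 0, inlier_ratio <= 1, sample_size >= 1)
  good <- inlier_ratio^sample_size
  if (good >= 1) {
    return(1L)
  }
  # log1p for accuracy when rho^K is tiny or near one
  s <- log1p(-confidence) / log1p(-good)
  as.integer(ceiling(s - 1e-12))
}

# Circle through three 2D points (circumcircle); NULL when collinear.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(c(ax, ay, bx, by, cx, cy, 1)))
  if (abs(d) < 1e-12 * scale^2) {
    return(NULL)
  }
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Algebraic least-squares circle fit
#'
#' Kasa fit: linear least squares on `x^2 + y^2 = 2 a x + 2 b y + c`. Used to
#' polish the RANSAC consensus set.
#'
#' @param points2d n x 2 matrix or data frame of 2D points.
#' @return List of class `"circle2d"` with `center` (length 2) and `radius`.
#' @export
fit_circle_lsq <- function(points2d) {
  pts <- as.matrix(points2d)
  if (ncol(pts) != 2L || nrow(pts) < 3L) {
    abort("circle fit needs an n x 2 set with n >= 3", class = "nsafit_validation")
  }
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  A <- cbind(2 * q, 1)
  rhs <- rowSums(q^2)
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    abort("circle fit is degenerate (collinear points)", class = "nsafit_degenerate")
  }
  center <- sol[1:2] + ctr
  radius <- sqrt(sol[3] + sum(sol[1:2]^2))
  structure(list(center = unname(center), radius = radius), class = "circle2d")
}

#' @export
print.circle2d <- function(x, ...) {
  cat(sprintf(
    "<circle2d> center (%.3f, %.3f) mm, radius %.3f mm\n",
    x$center[1], x$center[2], x$radius
  ))
  invisible(x)
}

#' Robust circle fit by random sample consensus
#'
#' Repeatedly draws minimal samples of three points, circumscribes a circle,
#' and scores it by the number of points whose absolute distance to the
#' circle is within `config$inlier_threshold`. The trial budget starts from
#' [ransac_trials()] at `inlier_ratio_floor` and adapts downwards as better
#' consensus sets are found, capped at `max_trials`. Ties on inlier count are
#' broken by smaller mean inlier residual, then by earlier trial, so the fit
#' is deterministic for a given seed. The best consensus set is polished with
#' [fit_circle_lsq()].
#'
#' @param points2d n x 2 matrix or data frame of 2D points (n >= 3).
#' @param config A [ransac_config()].
#' @return List of class `"circle2d_ransac"`: `circle` (a `"circle2d"`),
#'   `inliers` (logical mask), `n_trials`, and `inlier_ratio`.
#' @export
fit_circle_ransac <- function(points2d, config = ransac_config()) {
  pts <- as.matrix(points2d)
  if (ncol(pts) != 2L || nrow(pts) < 3L) {
    abort("RANSAC circle fit needs >= 3 2D points", class = "nsafit_validation")
  }
  n <- nrow(pts)
  thr <- config$inlier_threshold
  best <- NULL
  best_count <- -1L
  best_resid <- Inf
  budget <- min(
    config$max_trials,
    ransac_trials(config$confidence, config$inlier_ratio_floor, config$sample_size)
  )
  with_seed(config$seed, {
    trial <- 0L
    while (trial < budget) {
      trial <- trial + 1L
      idx <- sample.int(n, 3L)
      circ <- circumcircle(pts[idx[1], ], pts[idx[2], ], pts[idx[3], ])
      if (is.null(circ)) next
      d <- abs(sqrt((pts[, 1] - circ$center[1])^2 +
                      (pts[, 2] - circ$center[2])^2) - circ$radius)
      mask <- d <= thr
      cnt <- sum(mask)
      if (cnt >= config$sample_size) {
        resid <- mean(d[mask])
        if (cnt > best_count || (cnt == best_count && resid < best_resid)) {
          best <- mask
          best_count <- cnt
          best_resid <- resid
          ratio <- max(cnt / n, config$inlier_ratio_floor)
          budget <- min(
            budget,
            max(trial, ransac_trials(config$confidence, ratio, config$sample_size))
          )
        }
      }
    }
  })
  if (is.null(best)) {
    abort(
      "RANSAC found no consensus circle (all samples collinear or threshold too small)",
      class = "nsafit_fit_failure"
    )
  }
  circle <- fit_circle_lsq(pts[best, , drop = FALSE])
  # local optimization: alternate least-squares refit and inlier
  # reselection until the consensus set is stable, so the final model is
  # supported by the full annulus of points within the threshold rather
  # than the chance consensus of one minimal sample
  for (iter in seq_len(25L)) {
    d <- abs(sqrt((pts[, 1] - circle$center[1])^2 +
                    (pts[, 2] - circle$center[2])^2) - circle$radius)
    mask <- d <= thr
    if (sum(mask) < 3L || identical(mask, best)) break
    best <- mask
    circle <- fit_circle_lsq(pts[best, , drop = FALSE])
  }
  structure(
    list(
      circle = circle, inliers = best, n_trials = budget,
      inlier_ratio = sum(best) / n
    ),
    class = "circle2d_ransac"
  )
}

#' @export
print.circle2d_ransac <- function(x, ...) {
  cat(sprintf(
    "<circle2d_ransac> center (%.3f, %.3f), radius %.3f, %d/%d inliers, %d trials\n",
    x$circle$center[1], x$circle$center[2], x$circle$radius,
    sum(x$inliers), length(x$inliers), x$n_trials
  ))
  invisible(x)
}
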