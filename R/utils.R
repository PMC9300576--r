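# Small vector helpers shared across the geometry code. All 3-vectors are
# plain numeric length-3; point sets are n x 3 matrices in millimetres.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-300) {
    abort("cannot normalize a zero-length vector", class = "nsafit_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Coerce a cloud-like input (data frame with x,y,z or n x 3 matrix) to a matrix.
as_xyz_matrix <- function(points, arg = "points") {
  if (is.data.frame(points)) {
    need <- c("x", "y", "z")
    if (!all(need %in% names(points))) {
      abort(
        sprintf("`%s` must have columns x, y, z", arg),
        class = "nsafit_validation"
      )
    }
    points <- as.matrix(points[, need])
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    abort(sprintf("`%s` must be n x 3", arg), class = "nsafit_validation")
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    abort(
      sprintf("`%s` contains non-finite coordinates", arg),
      class = "nsafit_validation"
    )
  }
  points
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards,
# so seeded fits never disturb the global random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
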