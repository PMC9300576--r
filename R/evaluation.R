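confusion_counts <- function(pred, truth, num_classes) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length", class = "nsafit_validation")
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (any(pred < 0L | pred >= num_classes) || any(truth < 0L | truth >= num_classes)) {
    abort("labels must lie in [0, num_classes)", class = "nsafit_validation")
  }
  classes <- seq_len(num_classes) - 1L
  tibble::tibble(
    class = classes,
    tp = vapply(classes, function(c) sum(pred == c & truth == c), 0L),
    fp = vapply(classes, function(c) sum(pred == c & truth != c), 0L),
    fn = vapply(classes, function(c) sum(pred != c & truth == c), 0L)
  )
}

#' Segmentation agreement scores
#'
#' Per-class Dice coefficient `2 TP / (2 TP + FP + FN)` and intersection over
#' union `TP / (TP + FP + FN)` between a predicted and a reference labeling,
#' with macro (mean over classes) and micro (pooled counts) aggregates. A
#' class absent from both labelings is scored 1 by convention and excluded
#' from the macro means (the 0/0 ratio is undefined).
#'
#' @param pred,truth Integer label vectors of equal length (codes
#'   `0 .. num_classes - 1`).
#' @param num_classes Number of classes; default 3 (head, neck, shaft).
#' @return A tibble of class `"seg_scores"` with one row per class
#'   (`class`, `tp`, `fp`, `fn`, `dice`, `iou`, `present`); the aggregates
#'   are available via [glance.seg_scores()].
#' @examples
#' seg_scores(c(0, 0, 1, 1), c(0, 1, 1, 1), num_classes = 2)
#' @export
seg_scores <- function(pred, truth, num_classes = 3L) {
  cm <- confusion_counts(pred, truth, num_classes)
  cm$present <- (cm$tp + cm$fp + cm$fn) > 0L
  cm$dice <- ifelse(cm$present, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn), 1)
  cm$iou <- ifelse(cm$present, cm$tp / (cm$tp + cm$fp + cm$fn), 1)
  class(cm) <- c("seg_scores", class(cm))
  cm
}

#' @rdname seg_scores
#' @export
dice_scores <- function(pred, truth, num_classes = 3L) {
  s <- seg_scores(pred, truth, num_classes)
  setNames(s$dice, paste0("class_", s$class))
}

#' @rdname seg_scores
#' @export
miou_score <- function(pred, truth, num_classes = 3L) {
  glance(seg_scores(pred, truth, num_classes))$miou
}

#' Aggregate segmentation scores
#'
#' One-row summary of a [seg_scores()] table: `macro_dice` and `miou` are the
#' means of the per-class scores over the classes present in either labeling;
#' `micro_dice` and `micro_iou` pool the confusion counts over classes.
#'
#' @param x A `"seg_scores"` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.seg_scores <- function(x, ...) {
  p <- x[x$present, , drop = FALSE]
  tp <- sum(p$tp); fp <- sum(p$fp); fn <- sum(p$fn)
  tibble::tibble(
    macro_dice = mean(p$dice),
    miou = mean(p$iou),
    micro_dice = 2 * tp / (2 * tp + fp + fn),
    micro_iou = tp / (tp + fp + fn),
    n_classes_present = nrow(p)
  )
}

#' Two-sample Student's t-test
#'
#' Pooled-variance (equal-variance) two-sample t statistic with
#' `n1 + n2 - 2` degrees of freedom and a two-tailed p value — the test used
#' to compare neck-shaft-angle distributions between measurement methods.
#' Degenerate zero-variance inputs are handled explicitly: equal constant
#' samples give `t = 0, p = 1`; unequal constant samples give an infinite
#' statistic with `p = 0` and `infinite = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t_stat`, `p_value`, `df`, and `infinite`.
#' @examples
#' t_test_two_sample(1:5, 2:6) # t = -1, p ~ 0.347
#' @export
t_test_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each sample needs >= 2 values", class = "nsafit_validation")
  }
  df <- length(x) + length(y) - 2L
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_stat = 0, p_value = 1, df = df, infinite = FALSE))
    }
    return(list(
      t_stat = sign(mean(x) - mean(y)) * Inf, p_value = 0, df = df,
      infinite = TRUE
    ))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(
    t_stat = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter), infinite = FALSE
  )
}

#' Angle agreement between two measurement methods
#'
#' Per-pair absolute error `|ref - cand|` (degrees) and accuracy
#' `(1 - |(ref - cand) / ref|) * 100` (%), their means, and a two-sample
#' Student's t-test comparing the two angle lists — the agreement summary
#' used to compare the 2D, 3D and reference measurements.
#'
#' @param reference,candidate Equal-length numeric vectors of angles in
#'   degrees; `reference` must be strictly positive (it is the accuracy
#'   denominator).
#' @return A tibble of class `"angle_error_stats"` with columns `reference`,
#'   `candidate`, `error_deg`, `accuracy_pct`; summary via
#'   [glance.angle_error_stats()].
#' @examples
#' glance(angle_error_stats(c(130, 120), c(128.7, 121.2)))
#' @export
angle_error_stats <- function(reference, candidate) {
  if (length(reference) != length(candidate) || length(reference) == 0L) {
    abort("`reference` and `candidate` must be equal nonempty lengths",
          class = "nsafit_validation")
  }
  if (any(!is.finite(reference)) || any(!is.finite(candidate)) ||
      any(reference <= 0)) {
    abort("angles must be finite and reference angles positive",
          class = "nsafit_validation")
  }
  out <- tibble::tibble(
    reference = as.numeric(reference),
    candidate = as.numeric(candidate),
    error_deg = abs(reference - candidate),
    accuracy_pct = (1 - abs((reference - candidate) / reference)) * 100
  )
  class(out) <- c("angle_error_stats", class(out))
  out
}

#' Summarize angle agreement
#'
#' @param x An `"angle_error_stats"` tibble.
#' @param ... Unused.
#' @return One-row tibble: means and spreads of both angle lists, mean
#'   error and accuracy, and the two-sample t-test (`t_stat`, `p_value`);
#'   the layout mirrors a per-method agreement table (mean +/- SD, min-max,
#'   mean error, P, mean accuracy).
#' @export
glance.angle_error_stats <- function(x, ...) {
  tt <- if (nrow(x) >= 2L) {
    t_test_two_sample(x$reference, x$candidate)
  } else {
    list(t_stat = NA_real_, p_value = NA_real_, df = NA_real_)
  }
  tibble::tibble(
    n = nrow(x),
    ref_mean = mean(x$reference), ref_sd = sd(x$reference),
    ref_min = min(x$reference), ref_max = max(x$reference),
    cand_mean = mean(x$candidate), cand_sd = sd(x$candidate),
    cand_min = min(x$candidate), cand_max = max(x$candidate),
    mean_error_deg = mean(x$error_deg), sd_error_deg = sd(x$error_deg),
    min_error_deg = min(x$error_deg), max_error_deg = max(x$error_deg),
    mean_accuracy_pct = mean(x$accuracy_pct),
    t_stat = tt$t_stat, p_value = tt$p_value
  )
}

#' Cross-entropy of probabilistic labels
#'
#' Mean negative log-probability assigned to the true class:
#' `-(1/N) * sum_i log p[i, truth_i]` with one-hot truth, the loss used as a
#' probabilistic segmentation-quality metric. Probabilities are clipped below
#' at 1e-12 before the log.
#'
#' @param probs N x M matrix of per-sample class probabilities (rows sum to
#'   1 within 1e-9; columns are classes `0 .. M-1`).
#' @param truth Integer labels in `0 .. M-1`, length N.
#' @return Scalar loss (nats).
#' @examples
#' cross_entropy(matrix(rep(1 / 3, 6), 2, 3), c(0, 2)) # log(3)
#' @export
cross_entropy <- function(probs, truth) {
  probs <- as.matrix(probs)
  truth <- as.integer(truth)
  if (nrow(probs) != length(truth)) {
    abort("`probs` needs one row per label", class = "nsafit_validation")
  }
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    abort("each probability row must be nonnegative and sum to 1",
          class = "nsafit_validation")
  }
  if (any(truth < 0L | truth >= ncol(probs))) {
    abort("labels must lie in [0, ncol(probs))", class = "nsafit_validation")
  }
  p <- probs[cbind(seq_along(truth), truth + 1L)]
  mean(-log(pmax(p, 1e-12)))
}
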