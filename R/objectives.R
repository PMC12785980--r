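# Training objectives and decision thresholding for the multi-label task.
# These are the numeric reference implementations; the training loop applies
# the same formulas through the autodiff tape, and the two are cross-checked
# in the test suite.

#' Multi-label binary cross-entropy with logits
#'
#' Numerically stable sigmoid BCE, averaged over all classes (and samples
#' when given matrices).
#'
#' @param logits Numeric vector or matrix.
#' @param labels Binary vector or matrix of the same shape.
#' @return Scalar loss.
#' @export
bce_multilabel <- function(logits, labels) {
  if (length(logits) != length(labels)) abort("logits/labels length mismatch")
  if (!is_binary(labels)) abort("labels must be binary")
  z <- as.numeric(logits)
  y <- as.numeric(labels)
  # log(1 + exp(-|z|)) + max(z, 0) - z*y
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Focal-loss parameters with class-balanced weighting
#'
#' Per-class weights follow the effective number of samples:
#' `alpha_c = (1 - beta) / (1 - beta^{n_c})`, normalized to mean 1.
#'
#' @param gamma Focusing exponent (>= 0).
#' @param class_counts Per-class positive counts (length 14 or `n_classes`).
#' @param cb_beta Effective-number hyperparameter in `[0, 1)`.
#' @param alpha Optional explicit per-class weights; overrides the
#'   effective-number computation.
#' @return A list of class `cxr_focal_params` with the resolved `alpha`.
#' @export
focal_params <- function(gamma = 2, class_counts = NULL, cb_beta = 0.9999,
                         alpha = NULL) {
  stopifnot(gamma >= 0, cb_beta >= 0, cb_beta < 1)
  if (is.null(alpha)) {
    if (is.null(class_counts)) {
      alpha <- rep(1, cxr_n_classes())
    } else {
      eff <- (1 - cb_beta) / (1 - cb_beta^pmax(class_counts, 1))
      alpha <- eff / mean(eff)
    }
  }
  if (any(alpha < 0)) abort("alpha must be non-negative")
  structure(list(gamma = gamma, alpha = alpha, cb_beta = cb_beta),
            class = "cxr_focal_params")
}

#' Class-balanced focal loss
#'
#' `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)` with `p_t` the probability
#' assigned to the true class, averaged over entries. With `gamma = 0` and
#' unit weights this reduces to plain cross-entropy.
#'
#' @param probabilities Matrix (samples x classes) or vector of sigmoid
#'   probabilities in `(0, 1)`.
#' @param labels Binary matrix/vector of the same shape.
#' @param params A [focal_params()].
#' @return Scalar loss.
#' @export
class_balanced_focal <- function(probabilities, labels, params = focal_params()) {
  p <- as.matrix(probabilities)
  y <- as.matrix(labels)
  if (any(p <= 0 | p >= 1)) abort("probabilities must lie strictly in (0, 1)")
  if (!is_binary(y)) abort("labels must be binary")
  a <- params$alpha
  if (length(a) == 1L) a <- rep(a, ncol(p))
  if (length(a) != ncol(p)) abort("alpha length must match class count")
  pt <- p * y + (1 - p) * (1 - y)
  am <- matrix(a, nrow(p), ncol(p), byrow = TRUE)
  mean(-am * (1 - pt)^params$gamma * log(pt))
}

#' Soft Dice segmentation loss
#'
#' `1 - 2 |M \* Mhat| / (|M| + |Mhat| + eps)` with the soft intersection the
#' sum of elementwise products.
#'
#' @param pred Predicted mask, values in `[0, 1]`.
#' @param truth Binary ground-truth mask of the same shape.
#' @param eps Stabilizer (> 0).
#' @return Scalar in `[0, 1]` (up to eps effects).
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!all(dim(as.matrix(pred)) == dim(as.matrix(truth)))) {
    abort("pred and truth must have the same shape")
  }
  if (!is_binary(truth)) abort("truth mask must be binary")
  if (min(pred) < 0 || max(pred) > 1) abort("pred must lie in [0, 1]")
  inter <- sum(pred * truth)
  1 - 2 * inter / (sum(truth) + sum(pred) + eps)
}

#' Joint classification + segmentation objective
#'
#' @param cls_loss,seg_loss Scalars.
#' @param lambda Segmentation weight (>= 0).
#' @return `cls_loss + lambda * seg_loss`.
#' @export
joint_loss <- function(cls_loss, seg_loss, lambda = 0.5) {
  stopifnot(lambda >= 0)
  cls_loss + lambda * seg_loss
}

#' Per-class decision thresholds by validation grid search
#'
#' For each class the grid value maximizing per-class accuracy on the
#' validation set is chosen; ties break toward the smallest threshold. A
#' class with a single label value present falls back to the smallest grid
#' value.
#'
#' @param probabilities Validation probability matrix (samples x classes).
#' @param labels Binary label matrix of the same shape.
#' @param grid Candidate thresholds (default 0.05..0.95 step 0.01).
#' @return A tibble of class `cxr_thresholds` with `class`, `tau`,
#'   `accuracy`.
#' @export
select_thresholds <- function(probabilities, labels,
                              grid = seq(0.05, 0.95, by = 0.01)) {
  p <- as.matrix(probabilities)
  y <- as.matrix(labels)
  if (nrow(p) == 0L) abort("validation set is empty")
  stopifnot(all(dim(p) == dim(y)))
  cls <- colnames(p) %||% (if (ncol(p) == cxr_n_classes()) cxr_classes() else
    paste0("class_", seq_len(ncol(p))))
  res <- purrr::map_dfr(seq_len(ncol(p)), function(c_i) {
    yv <- y[, c_i]
    pv <- p[, c_i]
    if (length(unique(yv)) < 2L) {
      return(tibble::tibble(class = cls[c_i], tau = min(grid),
                            accuracy = mean((pv >= min(grid)) == yv)))
    }
    acc <- vapply(grid, function(t) mean((pv >= t) == yv), numeric(1))
    best <- which.max(acc) # which.max returns the first (smallest tau) maximum
    tibble::tibble(class = cls[c_i], tau = grid[best], accuracy = acc[best])
  })
  class(res) <- c("cxr_thresholds", class(res))
  res
}

#' Binarize probabilities with per-class thresholds
#'
#' Inclusive comparison: a probability exactly at its threshold predicts
#' positive.
#'
#' @param probabilities Matrix (samples x classes).
#' @param thresholds A `cxr_thresholds` tibble or numeric vector of
#'   per-class taus.
#' @return Binary integer matrix of the same shape.
#' @export
binarize <- function(probabilities, thresholds) {
  p <- as.matrix(probabilities)
  tau <- if (is.data.frame(thresholds)) thresholds$tau else as.numeric(thresholds)
  if (length(tau) != ncol(p)) abort("one threshold per class required")
  out <- 1L * (p >= matrix(tau, nrow(p), ncol(p), byrow = TRUE))
  dimnames(out) <- dimnames(p)
  out
}

#' Write / read thresholds as JSON
#'
#' @param thresholds A `cxr_thresholds` tibble.
#' @param path Output JSON path.
#' @return `path` (write) or the thresholds tibble (read).
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(as.list(setNames(thresholds$tau, thresholds$class)),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path)
  res <- tibble::tibble(class = names(x), tau = as.numeric(unlist(x)))
  class(res) <- c("cxr_thresholds", class(res))
  res
}
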