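# Classification and interpretability evaluation metrics.

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (both values must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!is_binary(labels)) abort("labels must be binary")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) abort("both label values must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class, macro and micro classification metrics
#'
#' Computes confusion counts per class plus accuracy, precision, recall and
#' F1; the macro rows are unweighted class means, the micro row pools the
#' confusion counts. Zero-denominator precision/recall/F1 are reported as 0
#' and flagged.
#'
#' @param predictions Binary matrix (samples x classes).
#' @param labels Binary matrix of the same shape.
#' @param scores Optional probability matrix for per-class AUROC.
#' @return A tibble of class `cxr_eval` with one row per class plus
#'   `macro` and `micro` rows.
#' @export
classification_metrics <- function(predictions, labels, scores = NULL) {
  p <- as.matrix(predictions)
  y <- as.matrix(labels)
  if (!all(dim(p) == dim(y))) abort("shape mismatch")
  if (!is_binary(p) || !is_binary(y)) abort("binary matrices required")
  cls <- colnames(y) %||% (if (ncol(y) == cxr_n_classes()) cxr_classes() else
    paste0("class_", seq_len(ncol(y))))
  per <- purrr::map_dfr(seq_len(ncol(y)), function(c_i) {
    tp <- sum(p[, c_i] == 1 & y[, c_i] == 1)
    fp <- sum(p[, c_i] == 1 & y[, c_i] == 0)
    fn <- sum(p[, c_i] == 0 & y[, c_i] == 1)
    tn <- sum(p[, c_i] == 0 & y[, c_i] == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    au <- if (!is.null(scores) && length(unique(y[, c_i])) == 2L) {
      auroc(scores[, c_i], y[, c_i])
    } else {
      NA_real_
    }
    tibble::tibble(
      class = cls[c_i], tp = tp, fp = fp, fn = fn, tn = tn,
      auroc = au, accuracy = (tp + tn) / nrow(y), precision = prec,
      recall = rec, f1 = f1, degenerate = (tp + fp == 0) || (tp + fn == 0)
    )
  })
  macro <- dplyr::summarise(
    per,
    class = "macro", tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
    tn = NA_integer_,
    auroc = mean(.data$auroc, na.rm = TRUE), accuracy = mean(.data$accuracy),
    precision = mean(.data$precision), recall = mean(.data$recall),
    f1 = mean(.data$f1), degenerate = any(.data$degenerate)
  )
  tp <- sum(per$tp)
  fp <- sum(per$fp)
  fn <- sum(per$fn)
  tn <- sum(per$tn)
  mprec <- if (tp + fp > 0) tp / (tp + fp) else 0
  mrec <- if (tp + fn > 0) tp / (tp + fn) else 0
  micro <- tibble::tibble(
    class = "micro", tp = tp, fp = fp, fn = fn, tn = tn,
    auroc = if (!is.null(scores) && length(unique(as.vector(y))) == 2L) {
      auroc(as.vector(scores), as.vector(y))
    } else {
      NA_real_
    },
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = mprec, recall = mrec,
    f1 = if (mprec + mrec > 0) 2 * mprec * mrec / (mprec + mrec) else 0,
    degenerate = (tp + fp == 0) || (tp + fn == 0)
  )
  out <- dplyr::bind_rows(per, macro, micro)
  class(out) <- c("cxr_eval", class(out))
  out
}

#' Intersection over anatomical mask
#'
#' Fraction of a non-negative saliency map's total activation mass that
#' falls inside a binary anatomical mask. With `top_frac` set, a thresholded
#' variant is used instead: the fraction of the top-X% activation pixels
#' inside the mask.
#'
#' @param heatmap Non-negative matrix.
#' @param mask Binary matrix (resized to the heatmap with nearest-neighbour
#'   interpolation if shapes differ).
#' @param top_frac Optional fraction in (0, 1] selecting the thresholded
#'   variant.
#' @return Fraction in `[0, 1]`.
#' @export
ioam <- function(heatmap, mask, top_frac = NULL) {
  if (any(heatmap < 0)) abort("heatmap must be non-negative")
  total <- sum(heatmap)
  if (total == 0) abort("IoAM undefined for an all-zero heatmap")
  if (!all(dim(mask) == dim(heatmap))) {
    mask <- resize_nearest(mask, nrow(heatmap), ncol(heatmap))
  }
  if (is.null(top_frac)) {
    return(sum(heatmap * mask) / total)
  }
  stopifnot(top_frac > 0, top_frac <= 1)
  k <- max(1L, ceiling(top_frac * length(heatmap)))
  thr <- sort(as.vector(heatmap), decreasing = TRUE)[k]
  sel <- heatmap >= thr
  sum(sel & mask == 1) / sum(sel)
}

#' Dice coefficient and IoU of two binary masks
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `iou = |A∩B| / |A∪B|`. Two empty masks
#' return `(1, 1)` by convention.
#'
#' @param a,b Binary matrices of equal shape.
#' @return A named list with `dice` and `iou`.
#' @export
dice_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("shape mismatch")
  if (!is_binary(a) || !is_binary(b)) abort("masks must be binary")
  sa <- sum(a)
  sb <- sum(b)
  inter <- sum(a * b)
  if (sa + sb == 0) {
    return(list(dice = 1, iou = 1))
  }
  union <- sa + sb - inter
  list(dice = 2 * inter / (sa + sb), iou = inter / union)
}
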