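# shared numeric helpers: image resizing, mask geometry, seeding

#' Bilinear resize of a numeric matrix
#'
#' Resizes `mat` to `out_h` x `out_w` using bilinear interpolation with
#' half-pixel centre alignment. Used to upsample saliency maps to image
#' resolution and to resize images during standardization.
#'
#' @param mat Numeric matrix.
#' @param out_h,out_w Output dimensions in pixels.
#' @return Numeric matrix of dimension `out_h` x `out_w`.
#' @export
resize_bilinear <- function(mat, out_h, out_w) {
  stopifnot(is.matrix(mat), out_h >= 1, out_w >= 1)
  h <- nrow(mat)
  w <- ncol(mat)
  if (h == out_h && w == out_w) {
    return(mat)
  }
  # source coordinates for each output pixel centre
  ry <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ry), 0), h - 1)
  x0 <- pmin(pmax(floor(rx), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ry - y0, 0), 1)
  wx <- pmin(pmax(rx - x0, 0), 1)
  a <- mat[y0 + 1, x0 + 1, drop = FALSE]
  b <- mat[y0 + 1, x1 + 1, drop = FALSE]
  cc <- mat[y1 + 1, x0 + 1, drop = FALSE]
  d <- mat[y1 + 1, x1 + 1, drop = FALSE]
  wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
  wym <- matrix(wy, out_h, out_w)
  top <- a * (1 - wxm) + b * wxm
  bot <- cc * (1 - wxm) + d * wxm
  top * (1 - wym) + bot * wym
}

#' Nearest-neighbour resize of a numeric matrix
#'
#' Used to bring binary masks to heatmap resolution without introducing
#' fractional values.
#'
#' @inheritParams resize_bilinear
#' @return Numeric matrix of dimension `out_h` x `out_w`.
#' @export
resize_nearest <- function(mat, out_h, out_w) {
  stopifnot(is.matrix(mat))
  h <- nrow(mat)
  w <- ncol(mat)
  if (h == out_h && w == out_w) {
    return(mat)
  }
  yi <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1), h)
  xi <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1), w)
  mat[yi, xi, drop = FALSE]
}

# filled-ellipse mask on an n x n (or h x w) pixel grid
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- y - cy
  dx <- x - cx
  if (theta != 0) {
    ct <- cos(theta)
    st <- sin(theta)
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
  } else {
    u <- dx
    v <- dy
  }
  (u / rx)^2 + (v / ry)^2 <= 1
}

# deterministic per-unit seed derived from a base seed and an index,
# kept inside the 32-bit integer range
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483629
  as.integer(s) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(x) all(x %in% c(0, 1))

# stable logistic
logistic <- function(x) 1 / (1 + exp(-x))
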