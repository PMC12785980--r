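# Ingestion pipeline: contrast-limited adaptive histogram equalization on the
# native-resolution gray image, then resize + 3-channel ImageNet
# standardization for the network.

#' CLAHE parameters
#'
#' @param tile_size Tile edge length in pixels (>= 2).
#' @param clip_factor Clip limit as a multiple of the mean histogram bin
#'   count (the classical beta; `Inf` disables clipping).
#' @param levels Number of gray levels L (>= 2); inputs must lie in
#'   `[0, L-1]`.
#' @return A list of class `cxr_clahe_params`.
#' @export
clahe_params <- function(tile_size = 8L, clip_factor = 3.0, levels = 256L) {
  stopifnot(tile_size >= 2L, clip_factor > 0, levels >= 2L)
  structure(
    list(tile_size = as.integer(tile_size), clip_factor = clip_factor,
         levels = as.integer(levels)),
    class = "cxr_clahe_params"
  )
}

# clipped, renormalized CDF mapping for one tile's pixel values
tile_mapping <- function(vals, levels, clip_factor) {
  hist_c <- tabulate(vals + 1L, nbins = levels)
  if (is.finite(clip_factor)) {
    limit <- clip_factor * mean(hist_c)
    excess <- sum(pmax(hist_c - limit, 0))
    hist_c <- pmin(hist_c, limit)
    # single-pass uniform redistribution of the clipped mass
    hist_c <- hist_c + excess / levels
  }
  cdf <- cumsum(hist_c) / sum(hist_c)
  cdf * (levels - 1)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is partitioned into a grid of `tile_size` tiles; each tile's
#' histogram is clipped at `clip_factor` times its mean bin count with the
#' excess redistributed uniformly, and the clipped CDF defines the tile's
#' intensity mapping `y = F(x) * (L - 1)`. Pixel values are remapped by
#' bilinear blending of the four neighbouring tile mappings, which removes
#' tile-boundary artifacts.
#'
#' @param image Numeric matrix with values in `[0, levels - 1]`.
#' @param params A [clahe_params()].
#' @return Matrix of the same shape with values in `[0, levels - 1]`.
#' @export
clahe <- function(image, params = clahe_params()) {
  stopifnot(is.matrix(image))
  L <- params$levels
  if (min(image) < 0 || max(image) > L - 1) {
    abort("image values must lie in [0, levels - 1]")
  }
  h <- nrow(image)
  w <- ncol(image)
  ts <- params$tile_size
  if (h < ts || w < ts) abort("image smaller than one tile")
  x <- pmin(pmax(round(image), 0), L - 1)
  nty <- max(1L, h %/% ts)
  ntx <- max(1L, w %/% ts)
  # tile boundaries (last tile absorbs the remainder)
  ybr <- c(seq(1L, by = ts, length.out = nty), h + 1L)
  xbr <- c(seq(1L, by = ts, length.out = ntx), w + 1L)
  maps <- array(0, c(nty, ntx, L))
  cy <- numeric(nty)
  cx <- numeric(ntx)
  for (i in seq_len(nty)) {
    rows <- ybr[i]:(ybr[i + 1L] - 1L)
    cy[i] <- mean(range(rows))
    for (j in seq_len(ntx)) {
      cols <- xbr[j]:(xbr[j + 1L] - 1L)
      if (i == 1L) cx[j] <- mean(range(cols))
      maps[i, j, ] <- tile_mapping(as.integer(x[rows, cols]), L,
                                   params$clip_factor)
    }
  }
  if (nty == 1L && ntx == 1L) {
    return(matrix(maps[1, 1, x + 1L], h, w))
  }
  # bilinear blend of the four neighbouring tile mappings per pixel
  py <- seq_len(h)
  px <- seq_len(w)
  iy <- findInterval(py, cy)
  ix <- findInterval(px, cx)
  i0 <- pmin(pmax(iy, 1L), nty)
  j0 <- pmin(pmax(ix, 1L), ntx)
  i1 <- pmin(i0 + 1L, nty)
  j1 <- pmin(j0 + 1L, ntx)
  i0 <- pmin(i0, i1)
  j0 <- pmin(j0, j1)
  wy <- ifelse(i1 > i0, (py - cy[i0]) / (cy[i1] - cy[i0]), 0)
  wx <- ifelse(j1 > j0, (px - cx[j0]) / (cx[j1] - cx[j0]), 0)
  wy <- clamp(wy, 0, 1)
  wx <- clamp(wx, 0, 1)
  lev <- as.integer(x) # column-major vector of levels
  rowi <- rep(seq_len(h), times = w)
  coli <- rep(seq_len(w), each = h)
  m00 <- maps[cbind(i0[rowi], j0[coli], lev + 1L)]
  m01 <- maps[cbind(i0[rowi], j1[coli], lev + 1L)]
  m10 <- maps[cbind(i1[rowi], j0[coli], lev + 1L)]
  m11 <- maps[cbind(i1[rowi], j1[coli], lev + 1L)]
  wyv <- wy[rowi]
  wxv <- wx[coli]
  out <- (1 - wyv) * ((1 - wxv) * m00 + wxv * m01) +
    wyv * ((1 - wxv) * m10 + wxv * m11)
  matrix(out, h, w)
}

#' Normalization parameters
#'
#' Defaults follow standard ImageNet statistics (mean 0.485/0.456/0.406,
#' std 0.229/0.224/0.225) with the preset's input resolution.
#'
#' @param target_size Output edge length in pixels.
#' @param channel_means,channel_stds Length-3 numeric vectors; stds must be
#'   strictly positive.
#' @return A list of class `cxr_norm_params`.
#' @export
norm_params <- function(target_size = 128L,
                        channel_means = c(0.485, 0.456, 0.406),
                        channel_stds = c(0.229, 0.224, 0.225)) {
  stopifnot(length(channel_means) == 3L, length(channel_stds) == 3L,
            all(channel_stds > 0))
  structure(
    list(target_size = as.integer(target_size),
         channel_means = channel_means, channel_stds = channel_stds),
    class = "cxr_norm_params"
  )
}

#' Resize and standardize a gray image for the network
#'
#' Bilinear resize to `target_size`, replication to three channels, then
#' per-channel `(x/255 - mean) / std`.
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param params A [norm_params()].
#' @return `target_size x target_size x 3` array.
#' @export
standardize <- function(image, params = norm_params()) {
  stopifnot(is.matrix(image), length(image) > 0)
  r <- resize_bilinear(image, params$target_size, params$target_size) / 255
  out <- array(0, c(params$target_size, params$target_size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- (r - params$channel_means[ch]) / params$channel_stds[ch]
  }
  out
}

#' Preprocess a phantom image end to end
#'
#' CLAHE at native resolution followed by [standardize()].
#'
#' @param image Gray matrix in `[0, 255]`.
#' @param clahe_par A [clahe_params()] or `NULL` to skip enhancement.
#' @param norm_par A [norm_params()].
#' @return Standardized `H x H x 3` array.
#' @export
preprocess_image <- function(image, clahe_par = clahe_params(),
                             norm_par = norm_params()) {
  if (!is.null(clahe_par)) image <- clahe(image, clahe_par)
  standardize(image, norm_par)
}
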