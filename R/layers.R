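# Neural layer primitives on the (N*H*W) x C row-major layout.
# Convolutions are evaluated as im2col gathers followed by one BLAS matmul;
# their index tables depend only on (H, W, kernel, stride, pad, N) and are
# cached per layer and batch size.

make_conv_idx <- function(H, W, k, stride, pad, N) {
  OH <- (H + 2L * pad - k) %/% stride + 1L
  OW <- (W + 2L * pad - k) %/% stride + 1L
  M <- N * OH * OW
  n <- rep(seq_len(N), each = OH * OW)
  orow <- rep(rep(seq_len(OH), each = OW), N)
  ocol <- rep(rep(seq_len(OW), OH), N)
  r0 <- (orow - 1L) * stride - pad
  c0 <- (ocol - 1L) * stride - pad
  zero_row <- N * H * W + 1L
  idx <- matrix(zero_row, M, k * k)
  o <- 0L
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      o <- o + 1L
      r <- r0 + ki
      cc <- c0 + kj
      ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
      idx[ok, o] <- (n[ok] - 1L) * H * W + (r[ok] - 1L) * W + cc[ok]
    }
  }
  list(idx = idx, OH = OH, OW = OW, M = M, n_vec = n)
}

make_upsample_idx <- function(h, w, f, N) {
  H <- h * f
  W <- w * f
  n <- rep(seq_len(N), each = H * W)
  orow <- rep(rep(seq_len(H), each = W), N)
  ocol <- rep(rep(seq_len(W), H), N)
  ir <- (orow - 1L) %/% f + 1L
  ic <- (ocol - 1L) %/% f + 1L
  (n - 1L) * h * w + (ir - 1L) * w + ic
}

# full convolution: w is (k*k*Cin) x Cout with offset-major column blocks
ad_conv2d <- function(tape, x, w, b, meta) {
  xv <- x$value
  C <- ncol(xv)
  xp <- rbind(xv, 0)
  K <- ncol(meta$idx)
  cols <- matrix(0, meta$M, K * C)
  for (o in seq_len(K)) {
    cols[, ((o - 1L) * C + 1L):(o * C)] <- xp[meta$idx[, o], , drop = FALSE]
  }
  y <- cols %*% w$value
  if (!is.null(b)) y <- sweep(y, 2, as.numeric(b$value), "+")
  out <- ad_node(tape, y)
  out$backward <- function(g) {
    ad_accum(w, crossprod(cols, g))
    if (!is.null(b)) ad_accum(b, matrix(colSums(g), 1))
    dcols <- g %*% t(w$value)
    dx <- matrix(0, nrow(xv), C)
    for (o in seq_len(K)) {
      dpart <- dcols[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
      agg <- rowsum(dpart, group = meta$idx[, o], reorder = FALSE)
      ridx <- as.integer(rownames(agg))
      keep <- ridx <= nrow(xv)
      dx[ridx[keep], ] <- dx[ridx[keep], ] + agg[keep, , drop = FALSE]
    }
    ad_accum(x, dx)
  }
  out
}

# depthwise convolution: w is (k*k) x C
ad_dwconv <- function(tape, x, w, meta) {
  xv <- x$value
  C <- ncol(xv)
  xp <- rbind(xv, 0)
  K <- ncol(meta$idx)
  gathered <- lapply(seq_len(K), function(o) xp[meta$idx[, o], , drop = FALSE])
  wv <- w$value
  y <- matrix(0, meta$M, C)
  for (o in seq_len(K)) {
    y <- y + gathered[[o]] * matrix(wv[o, ], meta$M, C, byrow = TRUE)
  }
  out <- ad_node(tape, y)
  out$backward <- function(g) {
    dw <- matrix(0, K, C)
    dx <- matrix(0, nrow(xv), C)
    for (o in seq_len(K)) {
      dw[o, ] <- colSums(g * gathered[[o]])
      dpart <- g * matrix(wv[o, ], meta$M, C, byrow = TRUE)
      agg <- rowsum(dpart, group = meta$idx[, o], reorder = FALSE)
      ridx <- as.integer(rownames(agg))
      keep <- ridx <= nrow(xv)
      dx[ridx[keep], ] <- dx[ridx[keep], ] + agg[keep, , drop = FALSE]
    }
    ad_accum(w, dw)
    ad_accum(x, dx)
  }
  out
}

ad_upsample_nearest <- function(tape, x, idx) {
  ad_gather_rows(tape, x, idx)
}

# multi-head scaled dot-product self-attention over per-sample blocks of
# `n_tokens` rows; q, k, v are (N*n_tokens) x D nodes, D = heads * head_dim
ad_mhsa_core <- function(tape, q, k, v, heads, n_tokens) {
  qv <- q$value
  kv <- k$value
  vv <- v$value
  D <- ncol(qv)
  stopifnot(D %% heads == 0L)
  dh <- D %/% heads
  N <- nrow(qv) %/% n_tokens
  scl <- 1 / sqrt(dh)
  yv <- matrix(0, nrow(qv), D)
  atts <- vector("list", N * heads)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * n_tokens + 1L):(n * n_tokens)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      s <- tcrossprod(qv[rows, cols, drop = FALSE], kv[rows, cols, drop = FALSE]) * scl
      s <- s - apply(s, 1, max)
      e <- exp(s)
      a <- e / rowSums(e)
      atts[[(n - 1L) * heads + h]] <- a
      yv[rows, cols] <- a %*% vv[rows, cols, drop = FALSE]
    }
  }
  out <- ad_node(tape, yv)
  out$backward <- function(g) {
    dq <- matrix(0, nrow(qv), D)
    dk <- matrix(0, nrow(qv), D)
    dv <- matrix(0, nrow(qv), D)
    for (n in seq_len(N)) {
      rows <- ((n - 1L) * n_tokens + 1L):(n * n_tokens)
      for (h in seq_len(heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        a <- atts[[(n - 1L) * heads + h]]
        go <- g[rows, cols, drop = FALSE]
        da <- tcrossprod(go, vv[rows, cols, drop = FALSE])
        dv[rows, cols] <- crossprod(a, go)
        ds <- a * (da - rowSums(da * a))
        dq[rows, cols] <- (ds %*% kv[rows, cols, drop = FALSE]) * scl
        dk[rows, cols] <- (crossprod(ds, qv[rows, cols, drop = FALSE])) * scl
      }
    }
    ad_accum(q, dq)
    ad_accum(k, dk)
    ad_accum(v, dv)
  }
  out
}

# inverted dropout; returns x untouched when not training
ad_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) {
    return(x)
  }
  m <- matrix(
    (runif(length(x$value)) >= rate) / (1 - rate),
    nrow(x$value), ncol(x$value)
  )
  out <- ad_node(tape, x$value * m)
  out$backward <- function(g) ad_accum(x, g * m)
  out
}

# ---- weight initialization -------------------------------------------------

trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  tries <- 0L
  while (any(bad) && tries < 10L) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
    tries <- tries + 1L
  }
  clamp(x, -2 * sd, 2 * sd)
}

init_conv_w <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), k * k * cin, cout)
}

init_dw_w <- function(k, c) {
  matrix(rnorm(k * k * c, 0, sqrt(2 / (k * k))), k * k, c)
}

init_linear_w <- function(din, dout, sd = 0.02) {
  matrix(trunc_normal(din * dout, sd), din, dout)
}
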