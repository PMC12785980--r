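# Minimal tape-based reverse-mode automatic differentiation on matrices.
#
# Every differentiable quantity is a node holding a numeric matrix `value`.
# Ops append nodes to a tape in evaluation order; ad_backward() sweeps the
# tape in reverse, calling each node's backward closure once its gradient is
# known. Feature maps are stored as (N*H*W) x C matrices with row-major
# spatial order: row index = (n-1)*H*W + (r-1)*W + c. Gradients are exact;
# finite differences appear only in tests as an independent oracle.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) {
    nd$grad <- g
  } else {
    nd$grad <- nd$grad + g
  }
  invisible(nd)
}

# Backpropagate from `root`, seeding with `seed` (defaults to 1 for scalars).
ad_backward <- function(tape, root, seed = NULL) {
  if (is.null(seed)) {
    stopifnot(length(root$value) == 1L)
    seed <- matrix(1, 1, 1)
  }
  root$grad <- seed
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) {
      nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

ad_grad <- function(nd) nd$grad

# ---- elementary ops --------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value
  bv <- b$value
  out <- ad_node(tape, av %*% bv)
  out$backward <- function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, t(av) %*% g)
  }
  out
}

# add a bias row-vector (length ncol) to every row
ad_add_bias <- function(tape, a, b) {
  bv <- as.numeric(b$value)
  out <- ad_node(tape, sweep(a$value, 2, bv, "+"))
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), 1))
  }
  out
}

ad_add <- function(tape, a, b) {
  out <- ad_node(tape, a$value + b$value)
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  }
  out
}

# a + s * b with constant scalar s
ad_axpy <- function(tape, a, b, s) {
  out <- ad_node(tape, a$value + s * b$value)
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, s * g)
  }
  out
}

ad_mul <- function(tape, a, b) {
  av <- a$value
  bv <- b$value
  out <- ad_node(tape, av * bv)
  out$backward <- function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  }
  out
}

ad_sigmoid <- function(tape, a) {
  s <- logistic(a$value)
  out <- ad_node(tape, s)
  out$backward <- function(g) ad_accum(a, g * s * (1 - s))
  out
}

ad_silu <- function(tape, a) {
  x <- a$value
  s <- logistic(x)
  out <- ad_node(tape, x * s)
  out$backward <- function(g) ad_accum(a, g * (s + x * s * (1 - s)))
  out
}

ad_gelu <- function(tape, a) {
  x <- a$value
  ph <- pnorm(x)
  out <- ad_node(tape, x * ph)
  out$backward <- function(g) ad_accum(a, g * (ph + x * dnorm(x)))
  out
}

ad_relu <- function(tape, a) {
  x <- a$value
  m <- x > 0
  out <- ad_node(tape, x * m)
  out$backward <- function(g) ad_accum(a, g * m)
  out
}

# rows of `idx` gather rows of a (with possible repetition)
ad_gather_rows <- function(tape, a, idx) {
  out <- ad_node(tape, a$value[idx, , drop = FALSE])
  out$backward <- function(g) {
    agg <- rowsum(g, group = idx, reorder = FALSE)
    d <- matrix(0, nrow(a$value), ncol(a$value))
    d[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, d)
  }
  out
}

ad_concat_cols <- function(tape, a, b) {
  na <- ncol(a$value)
  out <- ad_node(tape, cbind(a$value, b$value))
  out$backward <- function(g) {
    ad_accum(a, g[, seq_len(na), drop = FALSE])
    ad_accum(b, g[, -seq_len(na), drop = FALSE])
  }
  out
}

ad_slice_rows <- function(tape, a, rows) {
  out <- ad_node(tape, a$value[rows, , drop = FALSE])
  out$backward <- function(g) {
    d <- matrix(0, nrow(a$value), ncol(a$value))
    d[rows, ] <- g
    ad_accum(a, d)
  }
  out
}

ad_mean_all <- function(tape, a) {
  n <- length(a$value)
  out <- ad_node(tape, matrix(mean(a$value), 1, 1))
  out$backward <- function(g) {
    ad_accum(a, matrix(as.numeric(g) / n, nrow(a$value), ncol(a$value)))
  }
  out
}

# row-wise softmax
ad_softmax_rows <- function(tape, a) {
  x <- a$value
  m <- apply(x, 1, max)
  e <- exp(x - m)
  p <- e / rowSums(e)
  out <- ad_node(tape, p)
  out$backward <- function(g) {
    ad_accum(a, p * (g - rowSums(g * p)))
  }
  out
}

# layer normalization across columns of each row, with per-column affine
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  out <- ad_node(tape, sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+"))
  out$backward <- function(g) {
    d <- ncol(x)
    ad_accum(gamma, matrix(colSums(g * xhat), 1))
    ad_accum(beta, matrix(colSums(g), 1))
    gx <- sweep(g, 2, gv, "*")
    term <- gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)
    ad_accum(a, term * inv)
  }
  out
}

# batch normalization over rows, per column (channel); `bn` is a stateful
# environment carrying running statistics
ad_batchnorm <- function(tape, a, gamma, beta, bn, training, eps = 1e-5,
                         momentum = 0.1) {
  x <- a$value
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    bn$mean <- (1 - momentum) * bn$mean + momentum * mu
    bn$var <- (1 - momentum) * bn$var + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- bn$mean
    v <- bn$var
    xc <- sweep(x, 2, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  gv <- as.numeric(gamma$value)
  out <- ad_node(
    tape,
    sweep(sweep(xhat, 2, gv, "*"), 2, as.numeric(beta$value), "+")
  )
  out$backward <- function(g) {
    ad_accum(gamma, matrix(colSums(g * xhat), 1))
    ad_accum(beta, matrix(colSums(g), 1))
    gx <- sweep(g, 2, gv, "*")
    if (training) {
      t1 <- gx - matrix(colMeans(gx), n, ncol(x), byrow = TRUE) -
        xhat * matrix(colMeans(gx * xhat), n, ncol(x), byrow = TRUE)
      ad_accum(a, sweep(t1, 2, inv, "*"))
    } else {
      ad_accum(a, sweep(gx, 2, inv, "*"))
    }
  }
  out
}

# multiply each row of x (grouped by sample) by a per-sample gate row from s:
# x is (N*HW) x C, s is N x C, rows of x belong to sample n_vec
ad_channel_scale <- function(tape, x, s, n_vec) {
  sv <- s$value
  xe <- x$value
  se <- sv[n_vec, , drop = FALSE]
  out <- ad_node(tape, xe * se)
  out$backward <- function(g) {
    ad_accum(x, g * se)
    ad_accum(s, rowsum(g * xe, group = n_vec, reorder = TRUE))
  }
  out
}

ad_concat_rows <- function(tape, a, b) {
  na <- nrow(a$value)
  out <- ad_node(tape, rbind(a$value, b$value))
  out$backward <- function(g) {
    ad_accum(a, g[seq_len(na), , drop = FALSE])
    ad_accum(b, g[-seq_len(na), , drop = FALSE])
  }
  out
}

# per-sample global average pooling: (N*HW) x C -> N x C
ad_gap <- function(tape, x, n_vec, hw) {
  out <- ad_node(tape, rowsum(x$value, group = n_vec, reorder = TRUE) / hw)
  out$backward <- function(g) {
    ad_accum(x, g[n_vec, , drop = FALSE] / hw)
  }
  out
}
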