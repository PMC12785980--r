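test_that("paper-preset architectural arithmetic matches the published design", {
  sh <- model_shapes(hybrid_config("paper"))
  expect_equal(sh$n_patches, 576L)
  expect_equal(sh$seq_len, 577L)
  expect_equal(sh$head_dim, 48L)
  expect_equal(sh$fused_dim, 1280L)
  expect_equal(sh$n_logits, 14L)
  expect_equal(sh$ffn_dim, 1536L)
  expect_equal(sh$backbone_out_size, 12L) # 384 through the stride stack
})

test_that("desk-preset fused dimension is cnn_dim + vit_dim = 128", {
  sh <- model_shapes(hybrid_config("desk"))
  expect_equal(sh$image_size, 128L)
  expect_equal(sh$cnn_dim, 64L)
  expect_equal(sh$vit_dim, 64L)
  expect_equal(sh$fused_dim, 128L)
})

test_that("patchify_embed produces the right token geometry", {
  cfg <- hybrid_config("tiny") # patch 16
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  z <- patchify_embed(img, cfg, seed = 2)
  expect_equal(dim(z), c(5L, cfg$vit$dim)) # 4 patches + class token
  expect_error(patchify_embed(array(0, c(30, 30, 3)), cfg), "divisible")
})

test_that("zero image embeds to projection bias + positional embedding", {
  cfg <- hybrid_config("tiny")
  set.seed(11)
  params <- list(
    embed_w = matrix(rnorm(16^2 * 3 * cfg$vit$dim), 16^2 * 3, cfg$vit$dim),
    embed_b = matrix(rnorm(cfg$vit$dim), 1, cfg$vit$dim),
    cls = matrix(rnorm(cfg$vit$dim), 1, cfg$vit$dim),
    pos = matrix(rnorm(5 * cfg$vit$dim), 5, cfg$vit$dim)
  )
  z <- patchify_embed(array(0, c(32, 32, 3)), cfg, params)
  expect_equal(z[2, ], as.numeric(params$embed_b + params$pos[2, ]),
               tolerance = 1e-12)
  expect_equal(z[1, ], as.numeric(params$cls + params$pos[1, ]),
               tolerance = 1e-12)
})

test_that("single-token attention is the identity-weighted value projection", {
  cfg <- hybrid_config("tiny") # dim 16, 2 heads
  tok <- rmat(1, 16, seed = 3)
  set.seed(4)
  params <- list(wq = rmat(16, 16, 5), wk = rmat(16, 16, 6),
                 wv = rmat(16, 16, 7), wo = diag(16))
  out <- mhsa(tok, cfg, params)
  att <- attr(out, "attention")
  expect_equal(att[[1]][1, 1], 1)
  expect_equal(unname(out), unname(tok %*% params$wv), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mhsa matches a brute-force softmax(QK'/sqrt(d))V evaluation", {
  cfg <- hybrid_config("tiny")
  cfg$vit$dim <- 4L
  cfg$vit$heads <- 2L
  tok <- rmat(3, 4, seed = 8)
  params <- list(wq = rmat(4, 4, 9), wk = rmat(4, 4, 10), wv = rmat(4, 4, 11),
                 wo = rmat(4, 4, 12))
  out <- mhsa(tok, cfg, params)
  q <- tok %*% params$wq
  k <- tok %*% params$wk
  v <- tok %*% params$wv
  ref <- matrix(0, 3, 4)
  for (h in 1:2) {
    cols <- ((h - 1) * 2 + 1):(h * 2)
    s <- q[, cols] %*% t(k[, cols]) / sqrt(2)
    a <- exp(s) / rowSums(exp(s))
    ref[, cols] <- a %*% v[, cols]
  }
  ref <- ref %*% params$wo
  expect_equal(unname(out), ref, tolerance = 1e-10, ignore_attr = TRUE)
  # softmax rows sum to one
  for (a in attr(out, "attention")) expect_equal(rowSums(a), rep(1, 3))
})

test_that("attention is permutation-equivariant without positional input", {
  cfg <- hybrid_config("tiny")
  cfg$vit$dim <- 6L
  cfg$vit$heads <- 2L
  tok <- rmat(5, 6, seed = 13)
  params <- list(wq = rmat(6, 6, 14), wk = rmat(6, 6, 15), wv = rmat(6, 6, 16),
                 wo = rmat(6, 6, 17))
  perm <- c(3, 1, 5, 2, 4)
  out1 <- mhsa(tok, cfg, params)
  out2 <- mhsa(tok[perm, ], cfg, params)
  expect_equal(unname(out2), unname(out1[perm, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("squeeze-excitation gates behave as specified", {
  fmap <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  # zero-initialized weights give gates exactly 0.5
  out <- se_block(fmap, r = 2)
  expect_equal(attr(out, "gates"), rep(0.5, 4))
  expect_equal(out[2, 3, 1], fmap[2, 3, 1] * 0.5)
  # hand-set 2-channel toy against scalar evaluation
  f2 <- array(0, c(2, 2, 2))
  f2[, , 1] <- 1
  f2[, , 2] <- 2
  pars <- list(w1 = matrix(c(1, 0, 0, 1), 2, 2), b1 = matrix(0, 1, 2),
               w2 = matrix(c(1, 0, 0, -1), 2, 2), b2 = matrix(0, 1, 2))
  g <- attr(se_block(f2, 1, pars), "gates")
  sw <- function(x) x / (1 + exp(-x))
  expect_equal(g, c(1 / (1 + exp(-sw(1))), 1 / (1 + exp(sw(2)))),
               tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
  expect_error(se_block(fmap, r = 3), "divisible")
})

test_that("forward emits coherent multi-label and segmentation outputs", {
  cfg <- hybrid_config("tiny")
  m <- build_model(cfg, seed = 1)
  set.seed(21)
  imgs <- list(array(rnorm(32 * 32 * 3), c(32, 32, 3)),
               array(rnorm(32 * 32 * 3), c(32, 32, 3)))
  out <- forward(m, imgs)
  expect_equal(dim(out$logits), c(2L, 14L))
  expect_equal(out$probabilities, logistic <- 1 / (1 + exp(-out$logits)))
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  expect_equal(dim(out$seg_masks[[1]]), c(32L, 32L, 2L))
  expect_true(all(out$seg_masks[[1]] >= 0 & out$seg_masks[[1]] <= 1))
  expect_equal(dim(out$feature_maps[[1]])[3], cfg$head_channels)
})
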