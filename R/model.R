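# The dual-path hybrid network: an MBConv/SE convolutional backbone for local
# texture, a patch-token transformer branch for global context, feature
# fusion into a multi-label sigmoid head, and an auxiliary two-channel
# (lung, heart) segmentation decoder. Presets:
#   "paper" -- the full published configuration (384 px input, Table-scale
#              backbone, ViT-Base geometry: patch 16, dim 768, 16 heads,
#              8 blocks, FFN 1536), used for architectural checks;
#   "desk"  -- a reduced configuration (128 px, 64-dim branches) that trains
#              in minutes on one CPU for end-to-end phantom experiments;
#   "tiny"  -- a 32 px configuration for fast unit tests.

#' Hybrid CNN-ViT model configuration
#'
#' Builds the configuration list for the dual-path classifier. The backbone
#' is a stack of fused-MBConv and MBConv+SE stages; the transformer branch
#' consumes raw standardized pixels in non-overlapping patches. The
#' `"paper"` preset mirrors the published architecture; `"desk"` and
#' `"tiny"` are reduced presets for CPU-scale training and testing.
#'
#' @param preset One of `"desk"`, `"paper"`, `"tiny"`.
#' @param classes Number of output classes (default 14).
#' @param dropout Dropout rate on the fusion MLP during training.
#' @return A list of class `cxr_config`.
#' @export
hybrid_config <- function(preset = c("desk", "paper", "tiny"), classes = cxr_n_classes(),
                          dropout = 0.3) {
  preset <- match.arg(preset)
  stage <- function(kind, cin, cout, blocks, stride, k, t) {
    list(kind = kind, cin = cin, cout = cout, blocks = blocks,
         stride = stride, k = k, t = t)
  }
  cfg <- switch(preset,
    paper = list(
      image_size = 384L,
      stem = list(cin = 3L, cout = 24L, k = 3L, stride = 2L),
      stages = list(
        stage("fused", 24L, 24L, 2L, 1L, 3L, 1L),
        stage("fused", 24L, 48L, 3L, 2L, 3L, 4L),
        stage("mbse", 48L, 80L, 3L, 2L, 3L, 4L),
        stage("mbse", 80L, 128L, 4L, 2L, 3L, 4L),
        stage("mbse", 128L, 176L, 4L, 1L, 3L, 4L),
        stage("mbse", 176L, 256L, 4L, 2L, 3L, 4L),
        stage("mbse", 256L, 320L, 2L, 1L, 3L, 4L)
      ),
      head_channels = 512L,
      se_r = 4L,
      vit = list(patch = 16L, dim = 768L, heads = 16L, depth = 8L, mlp = 1536L),
      fusion_hidden = c(512L, 256L),
      seg_mid = 32L
    ),
    desk = list(
      image_size = 128L,
      stem = list(cin = 3L, cout = 16L, k = 3L, stride = 2L),
      stages = list(
        stage("fused", 16L, 32L, 1L, 2L, 3L, 2L),
        stage("mbse", 32L, 48L, 1L, 2L, 3L, 2L),
        stage("mbse", 48L, 64L, 1L, 1L, 3L, 2L)
      ),
      head_channels = 64L,
      se_r = 4L,
      vit = list(patch = 16L, dim = 64L, heads = 4L, depth = 2L, mlp = 128L),
      fusion_hidden = c(64L, 32L),
      seg_mid = 8L
    ),
    tiny = list(
      image_size = 32L,
      stem = list(cin = 3L, cout = 4L, k = 3L, stride = 2L),
      stages = list(
        stage("mbse", 4L, 8L, 1L, 2L, 3L, 2L)
      ),
      head_channels = 16L,
      se_r = 2L,
      vit = list(patch = 16L, dim = 16L, heads = 2L, depth = 1L, mlp = 32L),
      fusion_hidden = c(16L, 8L),
      seg_mid = 4L
    )
  )
  cfg$preset <- preset
  cfg$classes <- as.integer(classes)
  cfg$dropout <- dropout
  stopifnot(cfg$image_size %% cfg$vit$patch == 0L,
            cfg$vit$dim %% cfg$vit$heads == 0L)
  structure(cfg, class = "cxr_config")
}

#' Derived shapes of a model configuration
#'
#' Computes, without instantiating weights, the architectural arithmetic of a
#' configuration: patch count, token sequence length, per-head attention
#' dimension, fused feature dimension, logit dimension, FFN expansion width,
#' and the backbone output spatial size implied by the product of strides.
#'
#' @param cfg A `cxr_config`.
#' @return A one-row tibble.
#' @export
model_shapes <- function(cfg) {
  n_patches <- (cfg$image_size %/% cfg$vit$patch)^2
  strides <- c(cfg$stem$stride, vapply(cfg$stages, `[[`, integer(1), "stride"))
  out_size <- cfg$image_size %/% prod(strides)
  tibble::tibble(
    image_size = cfg$image_size,
    n_patches = as.integer(n_patches),
    seq_len = as.integer(n_patches + 1L),
    head_dim = cfg$vit$dim %/% cfg$vit$heads,
    cnn_dim = cfg$head_channels,
    vit_dim = cfg$vit$dim,
    fused_dim = cfg$head_channels + cfg$vit$dim,
    n_logits = cfg$classes,
    ffn_dim = cfg$vit$mlp,
    backbone_out_size = as.integer(out_size)
  )
}

# ---- parameter construction ------------------------------------------------

new_bn_state <- function(c) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, c)
  e$var <- rep(1, c)
  e
}

#' Build a hybrid model with freshly initialized weights
#'
#' Projections use truncated-normal initialization, convolutions fan-in
#' scaled normal; batch-norm scales start at 1. Deterministic for a fixed
#' seed.
#'
#' @param cfg A `cxr_config` from [hybrid_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `cxr_model` list with `config`, `params`, `bn` state and an
#'   index cache.
#' @export
build_model <- function(cfg, seed = 1L) {
  set.seed(seed)
  P <- list()
  BN <- list()
  addbn <- function(name, c) {
    P[[paste0(name, ".g")]] <<- matrix(1, 1, c)
    P[[paste0(name, ".b")]] <<- matrix(0, 1, c)
    BN[[name]] <<- new_bn_state(c)
  }
  addconv <- function(name, k, cin, cout, bias = TRUE) {
    P[[paste0(name, ".w")]] <<- init_conv_w(k, cin, cout)
    if (bias) P[[paste0(name, ".b")]] <<- matrix(0, 1, cout)
  }
  addlin <- function(name, din, dout, sd = 0.02) {
    P[[paste0(name, ".w")]] <<- init_linear_w(din, dout, sd)
    P[[paste0(name, ".b")]] <<- matrix(0, 1, dout)
  }

  addconv("stem", cfg$stem$k, cfg$stem$cin, cfg$stem$cout)
  addbn("stem.bn", cfg$stem$cout)
  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[[si]]
    cin <- st$cin
    for (bi in seq_len(st$blocks)) {
      pfx <- sprintf("s%d.b%d", si, bi)
      cout <- st$cout
      if (st$kind == "fused") {
        if (st$t > 1L) {
          ce <- cin * st$t
          addconv(paste0(pfx, ".exp"), st$k, cin, ce)
          addbn(paste0(pfx, ".exp.bn"), ce)
          addconv(paste0(pfx, ".proj"), 1L, ce, cout)
          addbn(paste0(pfx, ".proj.bn"), cout)
        } else {
          addconv(paste0(pfx, ".conv"), st$k, cin, cout)
          addbn(paste0(pfx, ".conv.bn"), cout)
        }
      } else {
        ce <- cin * st$t
        addconv(paste0(pfx, ".exp"), 1L, cin, ce)
        addbn(paste0(pfx, ".exp.bn"), ce)
        P[[paste0(pfx, ".dw.w")]] <- init_dw_w(st$k, ce)
        addbn(paste0(pfx, ".dw.bn"), ce)
        addlin(paste0(pfx, ".se.fc1"), ce, max(1L, ce %/% cfg$se_r),
               sd = sqrt(2 / ce))
        addlin(paste0(pfx, ".se.fc2"), max(1L, ce %/% cfg$se_r), ce,
               sd = sqrt(2 / max(1L, ce %/% cfg$se_r)))
        addconv(paste0(pfx, ".proj"), 1L, ce, cout)
        addbn(paste0(pfx, ".proj.bn"), cout)
      }
      cin <- cout
    }
  }
  last_c <- cfg$stages[[length(cfg$stages)]]$cout
  addconv("head", 1L, last_c, cfg$head_channels)
  addbn("head.bn", cfg$head_channels)

  v <- cfg$vit
  n_patches <- (cfg$image_size %/% v$patch)^2
  P[["vit.embed.w"]] <- init_linear_w(v$patch^2 * 3L, v$dim)
  P[["vit.embed.b"]] <- matrix(0, 1, v$dim)
  P[["vit.cls"]] <- matrix(trunc_normal(v$dim), 1, v$dim)
  P[["vit.pos"]] <- matrix(trunc_normal((n_patches + 1L) * v$dim),
                           n_patches + 1L, v$dim)
  for (l in seq_len(v$depth)) {
    pfx <- sprintf("vit.l%d", l)
    P[[paste0(pfx, ".ln1.g")]] <- matrix(1, 1, v$dim)
    P[[paste0(pfx, ".ln1.b")]] <- matrix(0, 1, v$dim)
    for (nm in c("q", "k", "v", "o")) {
      addlin(paste0(pfx, ".w", nm), v$dim, v$dim)
    }
    P[[paste0(pfx, ".ln2.g")]] <- matrix(1, 1, v$dim)
    P[[paste0(pfx, ".ln2.b")]] <- matrix(0, 1, v$dim)
    addlin(paste0(pfx, ".ffn1"), v$dim, v$mlp)
    addlin(paste0(pfx, ".ffn2"), v$mlp, v$dim)
  }
  P[["vit.ln.g"]] <- matrix(1, 1, v$dim)
  P[["vit.ln.b"]] <- matrix(0, 1, v$dim)

  fused <- cfg$head_channels + v$dim
  h <- cfg$fusion_hidden
  addlin("fc1", fused, h[1])
  addbn("fc1.bn", h[1])
  addlin("fc2", h[1], h[2])
  addbn("fc2.bn", h[2])
  addlin("fc3", h[2], cfg$classes)

  addconv("seg.c1", 1L, cfg$head_channels, cfg$seg_mid)
  addbn("seg.c1.bn", cfg$seg_mid)
  addconv("seg.c2", 3L, cfg$seg_mid, 2L)

  structure(
    list(config = cfg, params = P, bn = BN, cache = new.env(parent = emptyenv())),
    class = "cxr_model"
  )
}

# cached conv/upsample index tables keyed by layer geometry and batch size
cached_idx <- function(model, key, builder) {
  if (is.null(model$cache[[key]])) {
    model$cache[[key]] <- builder()
  }
  model$cache[[key]]
}

# ---- forward pass ----------------------------------------------------------

# convert a list of H x W x 3 arrays into the row-major (N*H*W) x 3 matrix
batch_to_rows <- function(images) {
  do.call(rbind, lapply(images, function(a) {
    stopifnot(length(dim(a)) == 3L, dim(a)[3] == 3L)
    cbind(as.vector(t(a[, , 1])), as.vector(t(a[, , 2])), as.vector(t(a[, , 3])))
  }))
}

rows_to_mat <- function(v, H, W) matrix(v, H, W, byrow = TRUE)

# full differentiable forward; returns nodes plus the parameter-node map
model_forward_tape <- function(model, x_rows, n, training = FALSE) {
  cfg <- model$config
  tape <- ad_tape()
  pn <- new.env(parent = emptyenv())
  P <- function(name) {
    if (is.null(pn[[name]])) pn[[name]] <- ad_leaf(tape, model$params[[name]])
    pn[[name]]
  }
  H <- cfg$image_size

  conv_bn_act <- function(x, name, k, stride, hin, act = "silu") {
    pad <- if (k > 1L) k %/% 2L else 0L
    meta <- cached_idx(
      model, sprintf("%s.%d.%d", name, hin, n),
      function() make_conv_idx(hin, hin, k, stride, pad, n)
    )
    y <- ad_conv2d(tape, x, P(paste0(name, ".w")), P(paste0(name, ".b")), meta)
    y <- ad_batchnorm(tape, y, P(paste0(name, ".bn.g")), P(paste0(name, ".bn.b")),
                      model$bn[[paste0(name, ".bn")]], training)
    if (act == "silu") y <- ad_silu(tape, y)
    if (act == "gelu") y <- ad_gelu(tape, y)
    list(x = y, h = meta$OH, n_vec = meta$n_vec)
  }

  # --- convolutional branch
  s <- conv_bn_act(ad_leaf(tape, x_rows), "stem", cfg$stem$k, cfg$stem$stride, H)
  hcur <- s$h
  x <- s$x
  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[[si]]
    cin <- st$cin
    for (bi in seq_len(st$blocks)) {
      pfx <- sprintf("s%d.b%d", si, bi)
      stride <- if (bi == 1L) st$stride else 1L
      x_in <- x
      h_in <- hcur
      if (st$kind == "fused") {
        if (st$t > 1L) {
          r <- conv_bn_act(x, paste0(pfx, ".exp"), st$k, stride, hcur)
          x <- r$x
          hcur <- r$h
          r <- conv_bn_act(x, paste0(pfx, ".proj"), 1L, 1L, hcur, act = "none")
          x <- r$x
        } else {
          r <- conv_bn_act(x, paste0(pfx, ".conv"), st$k, stride, hcur)
          x <- r$x
          hcur <- r$h
        }
      } else {
        r <- conv_bn_act(x, paste0(pfx, ".exp"), 1L, 1L, hcur)
        x <- r$x
        dw_meta <- cached_idx(
          model, sprintf("%s.dw.%d.%d", pfx, hcur, n),
          function() make_conv_idx(hcur, hcur, st$k, stride, st$k %/% 2L, n)
        )
        x <- ad_dwconv(tape, x, P(paste0(pfx, ".dw.w")), dw_meta)
        x <- ad_batchnorm(tape, x, P(paste0(pfx, ".dw.bn.g")),
                          P(paste0(pfx, ".dw.bn.b")),
                          model$bn[[paste0(pfx, ".dw.bn")]], training)
        x <- ad_silu(tape, x)
        hcur <- dw_meta$OH
        # squeeze-and-excitation channel gates on the depthwise output
        n_vec <- dw_meta$n_vec
        g0 <- ad_gap(tape, x, n_vec, hcur * hcur)
        g1 <- ad_silu(tape, ad_add_bias(
          tape, ad_matmul(tape, g0, P(paste0(pfx, ".se.fc1.w"))),
          P(paste0(pfx, ".se.fc1.b"))
        ))
        gates <- ad_sigmoid(tape, ad_add_bias(
          tape, ad_matmul(tape, g1, P(paste0(pfx, ".se.fc2.w"))),
          P(paste0(pfx, ".se.fc2.b"))
        ))
        x <- ad_channel_scale(tape, x, gates, n_vec)
        r <- conv_bn_act(x, paste0(pfx, ".proj"), 1L, 1L, hcur, act = "none")
        x <- r$x
      }
      if (stride == 1L && cin == st$cout) x <- ad_add(tape, x, x_in)
      cin <- st$cout
    }
  }
  r <- conv_bn_act(x, "head", 1L, 1L, hcur)
  feat <- r$x # retained feature maps A^k for saliency
  hs <- hcur
  n_vec_feat <- cached_idx(
    model, sprintf("nvec.%d.%d", hs, n),
    function() rep(seq_len(n), each = hs * hs)
  )
  f_cnn <- ad_gap(tape, feat, n_vec_feat, hs * hs)

  # --- transformer branch on raw standardized pixels
  v <- cfg$vit
  p <- v$patch
  np <- (H %/% p)^2
  pmeta <- cached_idx(
    model, sprintf("patch.%d.%d", H, n),
    function() make_conv_idx(H, H, p, p, 0L, n)
  )
  tok <- ad_conv2d(tape, ad_leaf(tape, x_rows), P("vit.embed.w"),
                   P("vit.embed.b"), pmeta)
  cls_rep <- ad_gather_rows(tape, P("vit.cls"), rep(1L, n))
  allr <- ad_concat_rows(tape, cls_rep, tok)
  # interleave: [cls_n, tokens_n] per sample
  perm <- cached_idx(model, sprintf("perm.%d.%d", np, n), function() {
    unlist(lapply(seq_len(n), function(i) {
      c(i, n + ((i - 1L) * np + 1L):(i * np))
    }))
  })
  z <- ad_gather_rows(tape, allr, perm)
  t_len <- np + 1L
  pos_rep <- ad_gather_rows(tape, P("vit.pos"), rep(seq_len(t_len), n))
  z <- ad_add(tape, z, pos_rep)
  for (l in seq_len(v$depth)) {
    pfx <- sprintf("vit.l%d", l)
    zn <- ad_layernorm(tape, z, P(paste0(pfx, ".ln1.g")), P(paste0(pfx, ".ln1.b")))
    qn <- ad_add_bias(tape, ad_matmul(tape, zn, P(paste0(pfx, ".wq.w"))),
                      P(paste0(pfx, ".wq.b")))
    kn <- ad_add_bias(tape, ad_matmul(tape, zn, P(paste0(pfx, ".wk.w"))),
                      P(paste0(pfx, ".wk.b")))
    vn <- ad_add_bias(tape, ad_matmul(tape, zn, P(paste0(pfx, ".wv.w"))),
                      P(paste0(pfx, ".wv.b")))
    att <- ad_mhsa_core(tape, qn, kn, vn, v$heads, t_len)
    att <- ad_add_bias(tape, ad_matmul(tape, att, P(paste0(pfx, ".wo.w"))),
                       P(paste0(pfx, ".wo.b")))
    z <- ad_add(tape, z, att)
    zn <- ad_layernorm(tape, z, P(paste0(pfx, ".ln2.g")), P(paste0(pfx, ".ln2.b")))
    ff <- ad_gelu(tape, ad_add_bias(
      tape, ad_matmul(tape, zn, P(paste0(pfx, ".ffn1.w"))), P(paste0(pfx, ".ffn1.b"))
    ))
    ff <- ad_add_bias(tape, ad_matmul(tape, ff, P(paste0(pfx, ".ffn2.w"))),
                      P(paste0(pfx, ".ffn2.b")))
    z <- ad_add(tape, z, ff)
  }
  z <- ad_layernorm(tape, z, P("vit.ln.g"), P("vit.ln.b"))
  cls_rows <- seq(1L, by = t_len, length.out = n)
  f_vit <- ad_slice_rows(tape, z, cls_rows)

  # --- fusion and multi-label head
  fused <- ad_concat_cols(tape, f_cnn, f_vit)
  h1 <- ad_add_bias(tape, ad_matmul(tape, fused, P("fc1.w")), P("fc1.b"))
  h1 <- ad_batchnorm(tape, h1, P("fc1.bn.g"), P("fc1.bn.b"), model$bn[["fc1.bn"]],
                     training)
  h1 <- ad_dropout(tape, ad_gelu(tape, h1), cfg$dropout, training)
  h2 <- ad_add_bias(tape, ad_matmul(tape, h1, P("fc2.w")), P("fc2.b"))
  h2 <- ad_batchnorm(tape, h2, P("fc2.bn.g"), P("fc2.bn.b"), model$bn[["fc2.bn"]],
                     training)
  h2 <- ad_dropout(tape, ad_gelu(tape, h2), cfg$dropout, training)
  logits <- ad_add_bias(tape, ad_matmul(tape, h2, P("fc3.w")), P("fc3.b"))

  # --- segmentation decoder (lung, heart) back to input resolution
  sg <- conv_bn_act(feat, "seg.c1", 1L, 1L, hs)
  f_total <- H %/% hs
  f2 <- min(4L, f_total)
  f1 <- f_total %/% f2
  xs <- sg$x
  hcur2 <- hs
  if (f1 > 1L) {
    up1 <- cached_idx(model, sprintf("up1.%d.%d.%d", hs, f1, n),
                      function() make_upsample_idx(hs, hs, f1, n))
    xs <- ad_upsample_nearest(tape, xs, up1)
    hcur2 <- hs * f1
  }
  c2meta <- cached_idx(model, sprintf("seg.c2.%d.%d", hcur2, n),
                       function() make_conv_idx(hcur2, hcur2, 3L, 1L, 1L, n))
  xs <- ad_conv2d(tape, xs, P("seg.c2.w"), P("seg.c2.b"), c2meta)
  if (f2 > 1L) {
    up2 <- cached_idx(model, sprintf("up2.%d.%d.%d", hcur2, f2, n),
                      function() make_upsample_idx(hcur2, hcur2, f2, n))
    xs <- ad_upsample_nearest(tape, xs, up2)
  }
  seg <- ad_sigmoid(tape, xs)

  list(
    tape = tape, logits = logits, seg = seg, feat = feat, fused = fused,
    hs = hs, n = n, param_nodes = pn
  )
}

#' Run the hybrid model on a batch of standardized images
#'
#' @param model A `cxr_model` from [build_model()].
#' @param images A list of `H x W x 3` standardized arrays (see
#'   [standardize()]), or a single such array.
#' @return An object of class `cxr_model_output`: per-class `logits` and
#'   `probabilities` (matrices, one row per image, columns named by class),
#'   `seg_masks` (per image, `H x W x 2` arrays in `[0,1]`, channels lung and
#'   heart), and `feature_maps` (per image, `h x w x K` retained backbone
#'   activations for saliency).
#' @export
forward <- function(model, images) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  x_rows <- batch_to_rows(images)
  fw <- model_forward_tape(model, x_rows, n, training = FALSE)
  H <- model$config$image_size
  hs <- fw$hs
  seg_v <- fw$seg$value
  feat_v <- fw$feat$value
  logits <- fw$logits$value
  cls <- if (ncol(logits) == cxr_n_classes()) cxr_classes() else
    paste0("class_", seq_len(ncol(logits)))
  colnames(logits) <- cls
  probs <- logistic(logits)
  seg_masks <- lapply(seq_len(n), function(i) {
    rows <- ((i - 1L) * H * H + 1L):(i * H * H)
    a <- array(0, c(H, H, 2L))
    a[, , 1] <- rows_to_mat(seg_v[rows, 1], H, H)
    a[, , 2] <- rows_to_mat(seg_v[rows, 2], H, H)
    a
  })
  feature_maps <- lapply(seq_len(n), function(i) {
    rows <- ((i - 1L) * hs * hs + 1L):(i * hs * hs)
    array(feat_v[rows, ], c(hs, hs, ncol(feat_v)))
  })
  structure(
    list(logits = logits, probabilities = probs, seg_masks = seg_masks,
         feature_maps = feature_maps),
    class = "cxr_model_output"
  )
}

# ---- exposed architectural operations --------------------------------------

#' Patch embedding of an image
#'
#' Splits a standardized image into non-overlapping `patch x patch` squares,
#' projects each flattened patch linearly into the embedding space, prepends
#' a learnable class token and adds positional embeddings.
#'
#' @param image `H x W x 3` array (or `H x W` matrix, replicated to three
#'   channels); `H` must be divisible by the patch size.
#' @param cfg A `cxr_config` (its `vit` block is used).
#' @param params Optional list with `embed_w`, `embed_b`, `cls`, `pos`;
#'   drawn with `seed` if missing.
#' @param seed Seed for parameter draw when `params` is missing.
#' @return `(n_patches + 1) x dim` token matrix; the class token is row 1.
#' @export
patchify_embed <- function(image, cfg, params = NULL, seed = 1L) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  H <- dim(image)[1]
  v <- cfg$vit
  if (H %% v$patch != 0L) {
    abort("image size must be divisible by the patch size")
  }
  np <- (H %/% v$patch)^2
  if (is.null(params)) {
    set.seed(seed)
    params <- list(
      embed_w = init_linear_w(v$patch^2 * 3L, v$dim),
      embed_b = matrix(0, 1, v$dim),
      cls = matrix(trunc_normal(v$dim), 1, v$dim),
      pos = matrix(trunc_normal((np + 1L) * v$dim), np + 1L, v$dim)
    )
  }
  x_rows <- batch_to_rows(list(image))
  meta <- make_conv_idx(H, H, v$patch, v$patch, 0L, 1L)
  xp <- rbind(x_rows, 0)
  K <- ncol(meta$idx)
  cols <- matrix(0, meta$M, K * 3L)
  for (o in seq_len(K)) {
    cols[, ((o - 1L) * 3L + 1L):(o * 3L)] <- xp[meta$idx[, o], , drop = FALSE]
  }
  tok <- sweep(cols %*% params$embed_w, 2, as.numeric(params$embed_b), "+")
  rbind(params$cls, tok) + params$pos
}

#' Multi-head self-attention over a token sequence
#'
#' Scaled dot-product attention: the sequence is projected per head into
#' queries, keys and values, attention weights are `softmax(Q K' / sqrt(d))`
#' with `d` the per-head dimension, and head outputs are concatenated and
#' re-projected.
#'
#' @param tokens `T x dim` matrix.
#' @param cfg A `cxr_config` (uses `vit$dim` and `vit$heads`).
#' @param params Optional list `wq`, `wk`, `wv`, `wo` (each `dim x dim`) and
#'   optional biases `bq`, `bk`, `bv`, `bo`.
#' @param seed Seed for the parameter draw when `params` is missing.
#' @return `T x dim` matrix with attribute `"attention"`, a list of per-head
#'   `T x T` weight matrices.
#' @export
mhsa <- function(tokens, cfg, params = NULL, seed = 1L) {
  v <- cfg$vit
  d <- v$dim
  if (ncol(tokens) != d) abort("token dimension must equal the embed dim")
  if (is.null(params)) {
    set.seed(seed)
    params <- list(
      wq = init_linear_w(d, d), wk = init_linear_w(d, d),
      wv = init_linear_w(d, d), wo = init_linear_w(d, d)
    )
  }
  zb <- matrix(0, 1, d)
  bq <- params$bq %||% zb
  bk <- params$bk %||% zb
  bv <- params$bv %||% zb
  bo <- params$bo %||% zb
  q <- sweep(tokens %*% params$wq, 2, as.numeric(bq), "+")
  k <- sweep(tokens %*% params$wk, 2, as.numeric(bk), "+")
  vv <- sweep(tokens %*% params$wv, 2, as.numeric(bv), "+")
  dh <- d %/% v$heads
  out <- matrix(0, nrow(tokens), d)
  att <- vector("list", v$heads)
  for (h in seq_len(v$heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
    s <- s - apply(s, 1, max)
    e <- exp(s)
    a <- e / rowSums(e)
    att[[h]] <- a
    out[, cols] <- a %*% vv[, cols, drop = FALSE]
  }
  res <- sweep(out %*% params$wo, 2, as.numeric(bo), "+")
  attr(res, "attention") <- att
  res
}

#' Squeeze-and-excitation channel gating
#'
#' Computes per-channel gates `sigmoid(W2 swish(W1 GAP(X)))` from globally
#' pooled features and rescales each channel of the input map.
#'
#' @param fmap `h x w x C` feature array.
#' @param r Channel reduction ratio (`C` must be divisible by `r`).
#' @param params Optional list `w1` (`C x C/r`), `b1`, `w2` (`C/r x C`),
#'   `b2`. Defaults to all-zero weights (gates exactly 0.5).
#' @return Gated `h x w x C` array with attribute `"gates"`.
#' @export
se_block <- function(fmap, r, params = NULL) {
  stopifnot(length(dim(fmap)) == 3L)
  C <- dim(fmap)[3]
  if (C %% r != 0L) abort("channels must be divisible by the reduction ratio")
  cr <- C %/% r
  if (is.null(params)) {
    params <- list(
      w1 = matrix(0, C, cr), b1 = matrix(0, 1, cr),
      w2 = matrix(0, cr, C), b2 = matrix(0, 1, C)
    )
  }
  gap <- apply(fmap, 3, mean)
  z <- as.numeric(gap %*% params$w1 + params$b1)
  z <- z * logistic(z) # swish
  gates <- logistic(as.numeric(z %*% params$w2 + params$b2))
  out <- fmap
  for (ch in seq_len(C)) out[, , ch] <- fmap[, , ch] * gates[ch]
  attr(out, "gates") <- gates
  out
}
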