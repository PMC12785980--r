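# Training: tape-level losses (mirroring the numeric reference
# implementations in objectives.R), a decoupled-weight-decay Adam optimizer,
# and the training loop with best-epoch checkpointing by validation
# micro-AUROC and validation-set threshold selection.

# stable log(sigmoid(s))
log_sigmoid <- function(s) {
  ifelse(s > 0, -log1p(exp(-s)), s - log1p(exp(s)))
}

# BCE-with-logits on the tape; gradient (sigmoid(z) - y) / n
ad_bce_logits <- function(tape, z, y) {
  zv <- z$value
  n <- length(zv)
  val <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  out <- ad_node(tape, matrix(val, 1, 1))
  out$backward <- function(g) {
    ad_accum(z, as.numeric(g) * (logistic(zv) - y) / n)
  }
  out
}

# class-balanced focal loss on the tape, computed from logits for stability;
# p_t = sigmoid((2y - 1) z)
ad_cb_focal <- function(tape, z, y, alpha, gamma) {
  zv <- z$value
  n <- length(zv)
  am <- matrix(alpha, nrow(zv), ncol(zv), byrow = TRUE)
  s <- (2 * y - 1) * zv
  pt <- logistic(s)
  lpt <- log_sigmoid(s)
  val <- mean(-am * (1 - pt)^gamma * lpt)
  out <- ad_node(tape, matrix(val, 1, 1))
  out$backward <- function(g) {
    dls <- am * (gamma * (1 - pt)^gamma * pt * lpt - (1 - pt)^(gamma + 1))
    ad_accum(z, as.numeric(g) * dls * (2 * y - 1) / n)
  }
  out
}

# soft Dice loss on the tape: mean over samples and channels
ad_dice <- function(tape, pred, truth, n, eps = 1e-6) {
  pv <- pred$value
  hw <- nrow(pv) %/% n
  ch <- ncol(pv)
  total <- 0
  terms <- vector("list", n * ch)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * hw + 1L):(i * hw)
    for (cc in seq_len(ch)) {
      m <- truth[rows, cc]
      p <- pv[rows, cc]
      inter <- sum(p * m)
      den <- sum(m) + sum(p) + eps
      total <- total + (1 - 2 * inter / den)
      terms[[(i - 1L) * ch + cc]] <- list(rows = rows, cc = cc, m = m,
                                          inter = inter, den = den)
    }
  }
  out <- ad_node(tape, matrix(total / (n * ch), 1, 1))
  out$backward <- function(g) {
    d <- matrix(0, nrow(pv), ch)
    for (t in terms) {
      d[t$rows, t$cc] <- d[t$rows, t$cc] +
        (-2 * t$m / t$den + 2 * t$inter / t$den^2)
    }
    ad_accum(pred, as.numeric(g) * d / (n * ch))
  }
  out
}

# ---- optimizer --------------------------------------------------------------

adamw_init <- function(params) {
  list(
    m = purrr::map(params, function(p) p * 0),
    v = purrr::map(params, function(p) p * 0),
    t = 0L
  )
}

# decoupled weight decay is applied to weight matrices only (not biases,
# norm scales/shifts, or the class/positional tokens)
adamw_decayed <- function(name) {
  grepl("\\.w$", name) && !grepl("^vit\\.(cls|pos)$", name)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && adamw_decayed(nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# ---- data plumbing ----------------------------------------------------------

# stack lung/heart masks of a study list into the (N*H*W) x 2 row-major truth
masks_to_rows <- function(studies) {
  do.call(rbind, lapply(studies, function(st) {
    cbind(as.vector(t(st$lung_mask)), as.vector(t(st$heart_mask)))
  }))
}

#' Train the hybrid model on phantom studies
#'
#' Joint objective: a multi-label classification loss (class-balanced focal
#' by default, plain BCE-with-logits optionally) plus `lambda` times the
#' two-channel (lung, heart) soft Dice segmentation loss. AdamW with a
#' constant learning rate. The cohort is split into training and validation
#' studies; after every epoch the validation micro-AUROC is logged and the
#' parameters of the best epoch are kept. Per-class decision thresholds are
#' fitted on the validation split by grid search.
#'
#' @param cohort List of `cxr_phantom_study` (see [generate_cohort()]).
#' @param config A `cxr_config`; its `image_size` drives preprocessing.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate (constant schedule).
#' @param weight_decay Decoupled weight decay.
#' @param lambda Segmentation weight in the joint objective.
#' @param loss `"cb_focal"` or `"bce"` as the classification term.
#' @param gamma Focal exponent.
#' @param cb_beta Effective-number hyperparameter for class weights.
#' @param clip_norm Global gradient-norm clip (`Inf` disables).
#' @param val_frac Fraction of studies held out for validation.
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @param use_clahe Apply CLAHE before standardization.
#' @param verbose Print per-epoch progress.
#' @return A `cxr_fit`: trained `model`, `history` tibble, `thresholds`,
#'   `best_epoch`, validation indices, and preprocessing parameters.
#' @export
train_model <- function(cohort, config = hybrid_config("desk"), epochs = 5L,
                        batch_size = 4L, lr = 5e-3, weight_decay = 1e-4,
                        lambda = 0.5, loss = c("cb_focal", "bce"), gamma = 2,
                        cb_beta = 0.9999, clip_norm = 5, val_frac = 0.2, seed = 1L,
                        use_clahe = TRUE, verbose = FALSE) {
  loss <- match.arg(loss)
  set.seed(seed)
  n <- length(cohort)
  n_val <- max(1L, round(val_frac * n))
  idx <- sample.int(n)
  val_idx <- sort(idx[seq_len(n_val)])
  tr_idx <- sort(idx[-seq_len(n_val)])

  np <- norm_params(target_size = config$image_size)
  cp <- if (use_clahe) clahe_params() else NULL
  imgs <- lapply(cohort, function(st) preprocess_image(st$image, cp, np))
  labels <- do.call(rbind, lapply(cohort, `[[`, "labels"))
  H <- config$image_size
  mask_rows_of <- function(ii) {
    masks_to_rows(lapply(cohort[ii], function(st) {
      list(
        lung_mask = resize_nearest(st$lung_mask, H, H),
        heart_mask = resize_nearest(st$heart_mask, H, H)
      )
    }))
  }

  model <- build_model(config, seed = seed)
  fp <- focal_params(gamma = gamma, class_counts = pmax(colSums(labels[tr_idx, ,
    drop = FALSE]), 1), cb_beta = cb_beta)
  opt <- adamw_init(model$params)
  history <- list()
  best <- list(auroc = -Inf, params = NULL, bn = NULL, epoch = 0L)

  predict_probs <- function(ii) {
    out <- matrix(0, length(ii), config$classes)
    bs <- 16L
    for (s in seq(1L, length(ii), by = bs)) {
      sel <- ii[s:min(s + bs - 1L, length(ii))]
      fw <- model_forward_tape(model, batch_to_rows(imgs[sel]), length(sel),
                               training = FALSE)
      out[match(sel, ii), ] <- logistic(fw$logits$value)
    }
    out
  }

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, length(ord), by = batch_size)) {
      sel <- ord[s:min(s + batch_size - 1L, length(ord))]
      nbatch <- length(sel)
      fw <- model_forward_tape(model, batch_to_rows(imgs[sel]), nbatch,
                               training = TRUE)
      y <- labels[sel, , drop = FALSE]
      cls_node <- if (loss == "cb_focal") {
        ad_cb_focal(fw$tape, fw$logits, y, fp$alpha, fp$gamma)
      } else {
        ad_bce_logits(fw$tape, fw$logits, y)
      }
      seg_truth <- mask_rows_of(sel)
      seg_node <- ad_dice(fw$tape, fw$seg, seg_truth, nbatch)
      total <- ad_axpy(fw$tape, cls_node, seg_node, lambda)
      ad_backward(fw$tape, total)
      grads <- purrr::compact(purrr::map(
        setNames(names(model$params), names(model$params)),
        function(nm) {
          nd <- fw$param_nodes[[nm]]
          if (is.null(nd)) NULL else nd$grad
        }
      ))
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gn > clip_norm) {
          grads <- purrr::map(grads, function(g) g * clip_norm / gn)
        }
      }
      st <- adamw_step(model$params, grads, opt, lr, weight_decay)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + total$value[1, 1]
      nb <- nb + 1L
    }
    probs <- predict_probs(val_idx)
    yv <- labels[val_idx, , drop = FALSE]
    micro <- if (length(unique(as.vector(yv))) == 2L) {
      auroc(as.vector(probs), as.vector(yv))
    } else {
      NA_real_
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = ep_loss / nb, val_micro_auroc = micro
    )
    if (!is.na(micro) && micro > best$auroc) {
      best <- list(
        auroc = micro, params = model$params,
        bn = lapply(model$bn, function(e) list(mean = e$mean, var = e$var)),
        epoch = ep
      )
    }
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val micro-AUROC %.4f",
                      ep, ep_loss / nb, micro))
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    for (nm in names(best$bn)) {
      model$bn[[nm]]$mean <- best$bn[[nm]]$mean
      model$bn[[nm]]$var <- best$bn[[nm]]$var
    }
  }
  probs <- predict_probs(val_idx)
  colnames(probs) <- if (config$classes == cxr_n_classes()) cxr_classes() else
    paste0("class_", seq_len(config$classes))
  thr <- select_thresholds(probs, labels[val_idx, , drop = FALSE])
  structure(
    list(
      model = model, history = dplyr::bind_rows(history), thresholds = thr,
      best_epoch = best$epoch, val_idx = val_idx, train_idx = tr_idx,
      norm_params = np, clahe_params = cp, seed = seed,
      loss = loss, lambda = lambda, lr = lr
    ),
    class = "cxr_fit"
  )
}

#' Save / load a fitted pipeline
#'
#' Single-file archive with the configuration embedded.
#'
#' @param fit A `cxr_fit`.
#' @param path File path.
#' @return `path`, or the restored `cxr_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  fit$model$bn <- lapply(fit$model$bn, function(e) list(mean = e$mean, var = e$var))
  fit$model$cache <- NULL
  saveRDS(fit, path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  fit$model$bn <- lapply(fit$model$bn, function(s) {
    e <- new.env(parent = emptyenv())
    e$mean <- s$mean
    e$var <- s$var
    e
  })
  fit$model$cache <- new.env(parent = emptyenv())
  fit
}

# ---- broom-style accessors --------------------------------------------------

#' @export
tidy.cxr_fit <- function(x, ...) x$history

#' @export
glance.cxr_fit <- function(x, ...) {
  tibble::tibble(
    preset = x$model$config$preset,
    n_params = sum(vapply(x$model$params, length, numeric(1))),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_micro_auroc = max(x$history$val_micro_auroc, na.rm = TRUE)
  )
}
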