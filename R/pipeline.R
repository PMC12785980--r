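# Pipeline orchestration: the four high-level commands (generate, train,
# explain, evaluate) as plain R functions, plus the YAML run-configuration
# loader. A thin command-line front-end over these functions ships in
# inst/exec/cxrreason.

#' Load and validate a run configuration
#'
#' Single YAML with `paths`, `preset`, `training`, `preprocess`, `reasoning`
#' and `seed` blocks; unknown top-level keys are rejected and referenced
#' files must exist.
#'
#' @param path YAML file (defaults to the packaged example).
#' @return Named list of class `cxr_run_config`.
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config.yaml", package = "cxrreason")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("paths", "preset", "training", "preprocess", "reasoning", "seed",
             "phantom")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(cfg$paths$rulebase) && !file.exists(cfg$paths$rulebase)) {
    abort(sprintf("rulebase file '%s' does not exist", cfg$paths$rulebase))
  }
  if (!is.null(cfg$preset) && !cfg$preset %in% c("desk", "paper", "tiny")) {
    abort("preset must be one of desk, paper, tiny")
  }
  structure(cfg, class = c("cxr_run_config", "list"))
}

#' Generate a phantom cohort on disk
#'
#' @param directory Output directory.
#' @param n Number of studies.
#' @param seed Cohort seed.
#' @param image_size Image edge length in pixels.
#' @param prevalence Per-class prevalence (scalar or 14-vector).
#' @param ... Further [phantom_spec()] arguments.
#' @return The manifest path (printed).
#' @export
cxr_generate <- function(directory, n, seed = 1L, image_size = 128L,
                         prevalence = 0.15, ...) {
  if (n < 1L) abort("n must be >= 1")
  spec <- phantom_spec(image_size = image_size, prevalence = prevalence,
                       seed = seed, ...)
  cohort <- generate_cohort(spec, n)
  man <- write_cohort(cohort, directory)
  message(man)
  invisible(man)
}

#' Train the pipeline on a cohort
#'
#' Trains the preset model on an in-memory cohort (or a directory written by
#' [cxr_generate()]), writes the best-epoch checkpoint, the fitted per-class
#' thresholds (JSON) and a per-epoch training log (CSV) to `out_dir`, and
#' returns the fit. The log records the config hash, seed and package
#' version for provenance.
#'
#' @param cohort List of phantom studies or a cohort directory.
#' @param out_dir Output directory for artifacts.
#' @param preset Model preset (`"desk"` default; `"paper"` is slow on CPU).
#' @param epochs,batch_size,lr,weight_decay,lambda,loss Training
#'   hyperparameters (see [train_model()]).
#' @param seed RNG seed.
#' @param verbose Print epoch progress.
#' @return A `cxr_fit` (invisibly) with `paths` attribute.
#' @export
cxr_train <- function(cohort, out_dir, preset = "desk", epochs = 5L,
                      batch_size = if (preset == "paper") 8L else 4L,
                      lr = if (preset == "paper") 1e-4 else 5e-3,
                      weight_decay = 1e-4, lambda = 0.5, loss = "cb_focal",
                      seed = 1L, verbose = FALSE) {
  if (is.character(cohort)) {
    abort_if_missing_cohort(cohort)
    cohort <- cohort_from_disk(cohort)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- hybrid_config(preset)
  fit <- train_model(cohort, cfg, epochs = epochs, batch_size = batch_size,
                     lr = lr, weight_decay = weight_decay, lambda = lambda,
                     loss = loss, seed = seed, verbose = verbose)
  ckpt <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(fit, ckpt)
  thr_path <- file.path(out_dir, "thresholds.json")
  write_thresholds(fit$thresholds, thr_path)
  log_path <- file.path(out_dir, "training_log.csv")
  log_tb <- fit$history
  log_tb$seed <- seed
  log_tb$preset <- preset
  log_tb$package_version <- as.character(utils::packageVersion("cxrreason"))
  log_tb$config_hash <- config_hash(cfg)
  readr::write_csv(log_tb, log_path)
  attr(fit, "paths") <- list(checkpoint = ckpt, thresholds = thr_path,
                             log = log_path)
  invisible(fit)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  # small rolling hash; provenance marker, not cryptographic
  sum(utf8ToInt(as.character(s)) * seq_along(utf8ToInt(as.character(s)))) %%
    1e9
}

abort_if_missing_cohort <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.json"))) {
    abort(sprintf("no cohort manifest under '%s'", dir))
  }
}

# reconstruct a minimal study list (images + masks + labels) from disk
cohort_from_disk <- function(directory) {
  dat <- read_cohort(directory)
  labs <- as.matrix(dat$labels[, cxr_classes()])
  purrr::map(seq_along(dat$studies), function(i) {
    st <- dat$studies[[i]]
    labels <- as.integer(labs[i, ])
    names(labels) <- cxr_classes()
    structure(
      list(image = st$image, lung_mask = st$lung_mask,
           heart_mask = st$heart_mask, thorax_mask = st$thorax_mask,
           labels = labels, lesions = NULL, index = i),
      class = "cxr_phantom_study"
    )
  })
}

# Grad-CAM maps for several classes from one shared forward pass
grad_cam_all <- function(model, image, class_indices) {
  x_rows <- batch_to_rows(list(image))
  fw <- model_forward_tape(model, x_rows, 1L, training = FALSE)
  n_cls <- model$config$classes
  H <- model$config$image_size
  hs <- fw$hs
  probs <- logistic(as.numeric(fw$logits$value))
  out <- purrr::map(class_indices, function(ci) {
    for (i in seq_len(fw$tape$n)) fw$tape$nodes[[i]]$grad <- NULL
    seed <- matrix(0, 1, n_cls)
    seed[1, ci] <- 1
    ad_backward(fw$tape, fw$logits, seed)
    alpha <- colMeans(ad_grad(fw$feat))
    hm_small <- pmax(fw$feat$value %*% alpha, 0)
    heat <- pmax(resize_bilinear(rows_to_mat(hm_small, hs, hs), H, H), 0)
    structure(
      list(heatmap = heat, heatmap_raw = rows_to_mat(hm_small, hs, hs),
           weights = alpha, class_index = ci, probabilities = probs),
      class = "cxr_gradcam"
    )
  })
  names(out) <- cxr_classes()[class_indices]
  out
}

# shared first half of the interpretive chain: preprocess, forward, per-class
# Grad-CAM, alignment, cue record
study_cues <- function(fit, study, rulebase, classes = cxr_classes()) {
  model <- fit$model
  img <- preprocess_image(study$image, fit$clahe_params, fit$norm_params)
  H <- model$config$image_size
  lung <- resize_nearest(study$lung_mask, H, H)
  heart <- resize_nearest(study$heart_mask, H, H)
  thorax <- resize_nearest(study$thorax_mask, H, H)
  cams <- grad_cam_all(model, img, match(classes, cxr_classes()))
  aligned <- purrr::map(cams, align_saliency, lung_mask = lung,
                        heart_mask = heart, thorax_mask = thorax)
  probs <- cams[[1]]$probabilities
  names(probs) <- cxr_classes()[seq_along(probs)]
  preds <- purrr::set_names(
    rulebase$predicates,
    vapply(rulebase$predicates, `[[`, character(1), "name")
  )
  bindings <- purrr::map_chr(preds, function(p) p$region %||% "lung")
  img_native <- resize_bilinear(study$image, H, H)
  cues <- compute_cues(aligned, lung, heart, thorax, image = img_native,
                       bindings = bindings)
  list(cues = cues, probs = probs, aligned = aligned, preds = preds,
       masks = list(lung = lung, heart = heart, thorax = thorax))
}

# second half of the interpretive chain shared by explanation and
# calibration: fuzzy beliefs per predicate (anatomical cue at the rulebase
# reference, classifier probability at the fitted decision threshold),
# conflict resolution, and the named value vector the rule engine consumes
# per-predicate fuzzy beliefs from a cue record and classifier probabilities;
# cheap, so calibration can re-evaluate beliefs without re-running Grad-CAM.
# The anatomical cue is referenced at the predicate's tau_ref; the classifier
# cue is log(p_c / tau_c) referenced at 0 (probability relative to the fitted
# class threshold: sigmoid outputs are compressed near the operating point,
# so the ratio carries the evidence). Per-predicate reliability weights
# (w_anat, w_cls), when present in the rulebase (set by calibration),
# override the global weights.
beliefs_from_cues <- function(cue_vals, probs, rulebase, tau_fit,
                              classes = cxr_classes()) {
  preds <- purrr::set_names(
    rulebase$predicates,
    vapply(rulebase$predicates, `[[`, character(1), "name")
  )
  beta <- rulebase$fuzzy$beta %||% 10
  beta_cls <- rulebase$fuzzy$beta_classifier %||% 2
  purrr::map_dfr(names(preds), function(nm) {
    if (!nm %in% classes) {
      return(NULL)
    }
    p <- preds[[nm]]
    conf <- cue_vals[[p$conf_cue]]
    tau_c <- unname(tau_fit[nm]) %||% 0.5
    if (is.null(tau_c) || is.na(tau_c)) tau_c <- 0.5
    tibble::tibble(
      predicate = nm,
      cue = c(p$conf_cue, "classifier_probability"),
      mu = c(fuzzy_membership(conf, beta, p$tau_ref %||% 0.5),
             fuzzy_membership(log(unname(probs[nm]) / tau_c), beta_cls, 0)),
      weight = c(p$w_anat %||% rulebase$weights$anatomical %||% 1,
                 p$w_cls %||% rulebase$weights$classifier %||% 1)
    )
  })
}

study_eval <- function(fit, study, rulebase, classes = cxr_classes()) {
  sc <- study_cues(fit, study, rulebase, classes)
  cue_vals <- setNames(sc$cues$value, sc$cues$cue)
  probs <- sc$probs
  tau_fit <- setNames(fit$thresholds$tau, fit$thresholds$class)
  beliefs <- beliefs_from_cues(cue_vals, probs, rulebase, tau_fit, classes)
  resolved <- resolve_conflicts(beliefs, rulebase$conflicts, NULL,
                                rulebase$conflict_penalty %||% 0.5)
  mu_vals <- setNames(
    resolved$mu_final,
    paste0("mu_", gsub(" ", "_", tolower(resolved$predicate)))
  )
  p_vals <- setNames(unname(probs),
                     paste0("p_", gsub(" ", "_", tolower(names(probs)))))
  c(sc, list(beliefs = resolved, cue_vals = cue_vals,
             values = c(cue_vals, mu_vals, p_vals)))
}

#' Calibrate rulebase reference levels and rule gates on validation studies
#'
#' The fuzzy reference levels and rule thresholds of this method are
#' empirical quantities; this fits them on calibration studies (typically the
#' validation split). Two steps:
#' \enumerate{
#'   \item each predicate's `tau_ref` becomes the median of its confidence
#'     cue over the calibration studies, so membership 0.5 marks the typical
#'     activation level (the cardiothoracic-ratio reference stays at the
#'     conventional 0.5 cutoff);
#'   \item each rule's membership gate (`mu_*` antecedent threshold) becomes
#'     the median of the calibration distribution of `mu_final` for its
#'     consequent: above-typical support instantiates a candidate hypothesis
#'     (hypothesis generation is sensitivity-first; prioritization and the
#'     reported probabilities do the discrimination).
#' }
#'
#' @param rulebase A `cxr_rulebase`.
#' @param fit A `cxr_fit`.
#' @param studies List of phantom studies used for calibration (labels are
#'   used only to estimate per-class prevalence for the gate quantile).
#' @return The updated `cxr_rulebase` (with a `calibrated` flag).
#' @export
calibrate_rulebase <- function(rulebase, fit, studies) {
  # one expensive pass (Grad-CAM cue extraction); everything after reuses it
  scs <- purrr::map(studies, function(st) study_cues(fit, st, rulebase))
  cue_mat <- purrr::map(scs, function(s) setNames(s$cues$value, s$cues$cue))
  prob_mat <- do.call(rbind, purrr::map(scs, "probs"))
  labels <- do.call(rbind, purrr::map(studies, `[[`, "labels"))
  tau_fit <- setNames(fit$thresholds$tau, fit$thresholds$class)

  # 1. reference levels: per-cue median over calibration studies
  all_cues <- names(cue_mat[[1]])
  refs <- vapply(all_cues, function(cn) {
    stats::median(vapply(cue_mat, `[[`, numeric(1), cn))
  }, numeric(1))
  rulebase$predicates <- purrr::map(rulebase$predicates, function(p) {
    if (p$conf_cue != "cardiothoracic_ratio" && p$conf_cue %in% names(refs)) {
      p$tau_ref <- as.numeric(refs[[p$conf_cue]])
    }
    p
  })

  # 2. reliability weights: per-cue Gini (2*AUROC - 1) of the cue for its
  # predicate's label over the calibration studies, floored at 0.05
  gini <- function(v, y) {
    if (length(unique(y)) < 2L) {
      return(NA_real_)
    }
    max(2 * auroc(v, y) - 1, 0)
  }
  rulebase$predicates <- purrr::map(rulebase$predicates, function(p) {
    nm <- p$name
    if (!nm %in% colnames(labels)) {
      return(p)
    }
    y <- labels[, nm]
    va <- vapply(cue_mat, `[[`, numeric(1), p$conf_cue)
    vc <- prob_mat[, nm]
    ga <- gini(va, y)
    gc <- gini(vc, y)
    if (!is.na(ga)) p$w_anat <- max(ga, 0.05)
    if (!is.na(gc)) p$w_cls <- max(gc, 0.05)
    p
  })

  # 3. rule gates: median of the calibration distribution of mu_final under
  # the recentred references and fitted weights
  mu_tbl <- purrr::map_dfr(seq_along(scs), function(i) {
    b <- beliefs_from_cues(cue_mat[[i]], prob_mat[i, ], rulebase, tau_fit)
    resolve_conflicts(b, rulebase$conflicts, NULL,
                      rulebase$conflict_penalty %||% 0.5)
  })
  rulebase$rules <- purrr::map(rulebase$rules, function(r) {
    key <- paste0("mu_", gsub(" ", "_", tolower(r$consequent)))
    mus <- mu_tbl$mu_final[mu_tbl$predicate == r$consequent]
    if (!length(mus)) {
      return(r)
    }
    gate <- as.numeric(stats::median(mus))
    r$antecedents <- purrr::map(r$antecedents, function(a) {
      if (a$cue == key) a$threshold <- gate
      a
    })
    r
  })
  rulebase$calibrated <- TRUE
  rulebase
}

#' Explain one study: saliency, cues, fuzzy reasoning, report
#'
#' Runs the full interpretive chain for a study: preprocessing, forward
#' pass, per-class Grad-CAM, anatomical alignment and region energies, cue
#' extraction, fuzzy memberships (anatomical cue referenced at the rulebase
#' level, classifier probability referenced at the fitted decision threshold
#' tau_c, weighted per the rulebase), conflict resolution, Horn-clause rule
#' evaluation, softmax ranking, and report generation.
#'
#' @param fit A `cxr_fit` from [train_model()]/[cxr_train()].
#' @param study A `cxr_phantom_study` (or list with `image` and the three
#'   masks).
#' @param rulebase A `cxr_rulebase` (packaged default when `NULL`).
#' @param classes Class names to explain; default all fourteen.
#' @return A list of class `cxr_explanation`: `report`, `ranked`, `fired`,
#'   `beliefs`, `cues`, `aligned` (per-class aligned saliency),
#'   `probabilities`.
#' @export
explain_study <- function(fit, study, rulebase = NULL, classes = cxr_classes()) {
  if (is.null(rulebase)) rulebase <- cxr_rulebase()
  bad <- setdiff(classes, cxr_classes())
  if (length(bad)) abort(sprintf("unknown class name: %s", bad[1]))
  se <- study_eval(fit, study, rulebase, classes)
  cues <- se$cues
  probs <- se$probs
  aligned <- se$aligned
  resolved <- se$beliefs
  values <- se$values
  cue_vals <- se$cue_vals
  rules <- purrr::keep(rulebase$rules, function(r) r$consequent %in% classes)
  fired <- evaluate_rules(values, rules)
  energies <- setNames(
    cue_vals[paste0("activation_", gsub(" ", "_", tolower(classes)))],
    classes
  )
  if (nrow(fired) > 0L) {
    s <- setNames(fired$confidence, fired$predicate)
    ranked <- rank_hypotheses(s, rulebase$ranking$alpha %||% 5)
  } else {
    ranked <- tibble::tibble(predicate = character(), score = numeric(),
                             probability = numeric(), rank = integer())
  }
  report <- generate_report(
    ranked, fired, rulebase,
    metadata = list(study_index = study$index %||% NA_integer_,
                    classifier_probabilities = as.list(probs)),
    energies = energies
  )
  structure(
    list(report = report, ranked = ranked, fired = fired, beliefs = resolved,
         cues = cues, aligned = aligned, probabilities = probs,
         masks = se$masks),
    class = "cxr_explanation"
  )
}

#' Explain a study and write artifacts to disk
#'
#' Per requested class (default: classes whose probability clears the fitted
#' threshold): a semi-transparent Grad-CAM overlay PNG and the aligned map;
#' plus the JSON report for the study.
#'
#' @param fit A `cxr_fit`.
#' @param study Phantom study.
#' @param out_dir Output directory.
#' @param classes Optional class names; default thresholded classes.
#' @param rulebase Optional `cxr_rulebase`.
#' @return The explanation (invisibly); artifacts under `out_dir`.
#' @export
cxr_explain <- function(fit, study, out_dir, classes = NULL, rulebase = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expl <- explain_study(fit, study, rulebase)
  if (is.null(classes)) {
    tau <- setNames(fit$thresholds$tau, fit$thresholds$class)
    classes <- names(expl$probabilities)[
      expl$probabilities >= tau[names(expl$probabilities)]
    ]
  }
  bad <- setdiff(classes, cxr_classes())
  if (length(bad)) abort(sprintf("unknown class name: %s", bad[1]))
  H <- fit$model$config$image_size
  base <- resize_bilinear(study$image, H, H) / 255
  for (cl in classes) {
    amap <- expl$aligned[[cl]]$aligned_map
    overlay <- array(0, c(H, H, 3L))
    overlay[, , 1] <- clamp(base + 0.6 * amap, 0, 1) # red channel carries saliency
    overlay[, , 2] <- base
    overlay[, , 3] <- base
    key <- gsub(" ", "_", tolower(cl))
    png::writePNG(overlay, file.path(out_dir, sprintf("overlay_%s.png", key)))
    png::writePNG(clamp(amap, 0, 1),
                  file.path(out_dir, sprintf("aligned_%s.png", key)))
  }
  write_report(expl$report, file.path(out_dir, "report.json"))
  invisible(expl)
}

#' Evaluate a fitted pipeline on a test cohort
#'
#' Classification metrics per class plus macro and micro rows (written as
#' CSV), and a saliency-agreement table (IoAM of each class's aligned
#' Grad-CAM map against the lung+heart anatomy, and Dice/IoU of the
#' predicted lung and heart segmentation masks against ground truth).
#'
#' @param fit A `cxr_fit`.
#' @param cohort Test cohort (list of phantom studies).
#' @param out_dir Optional output directory for `evaluation.csv` and
#'   `saliency_agreement.csv`.
#' @param saliency Compute the saliency-agreement table (one Grad-CAM per
#'   positive class per study; slower).
#' @param max_saliency_studies Cap on studies used for the saliency table.
#' @return List with `metrics` (a `cxr_eval` tibble) and `saliency`
#'   (tibble or `NULL`).
#' @export
cxr_evaluate <- function(fit, cohort, out_dir = NULL, saliency = FALSE,
                         max_saliency_studies = 25L) {
  model <- fit$model
  imgs <- lapply(cohort, function(st) {
    preprocess_image(st$image, fit$clahe_params, fit$norm_params)
  })
  labels <- do.call(rbind, lapply(cohort, `[[`, "labels"))
  probs <- matrix(0, length(cohort), model$config$classes)
  segs <- vector("list", length(cohort))
  bs <- 16L
  for (s in seq(1L, length(cohort), by = bs)) {
    sel <- s:min(s + bs - 1L, length(cohort))
    out <- forward(model, imgs[sel])
    probs[sel, ] <- out$probabilities
    segs[sel] <- out$seg_masks
  }
  colnames(probs) <- colnames(labels)
  preds <- binarize(probs, fit$thresholds)
  metrics <- classification_metrics(preds, labels, scores = probs)

  sal <- NULL
  if (saliency) {
    H <- model$config$image_size
    n_use <- min(length(cohort), max_saliency_studies)
    rows <- purrr::map_dfr(seq_len(n_use), function(i) {
      st <- cohort[[i]]
      lung <- resize_nearest(st$lung_mask, H, H)
      heart <- resize_nearest(st$heart_mask, H, H)
      anatomy <- 1 * ((lung + heart) > 0)
      pos <- which(st$labels == 1L)
      if (!length(pos)) {
        return(NULL)
      }
      cams <- grad_cam_all(model, imgs[[i]], pos)
      seg <- segs[[i]]
      d_lung <- dice_iou(1 * (seg[, , 1] >= 0.5), lung)
      d_heart <- dice_iou(1 * (seg[, , 2] >= 0.5), heart)
      purrr::map_dfr(names(cams), function(cl) {
        hm <- cams[[cl]]$heatmap
        tibble::tibble(
          study = i, class = cl,
          ioam = if (sum(hm) > 0) ioam(hm, anatomy) else NA_real_,
          dice_lung = d_lung$dice, iou_lung = d_lung$iou,
          dice_heart = d_heart$dice, iou_heart = d_heart$iou
        )
      })
    })
    sal <- rows %>%
      dplyr::group_by(.data$class) %>%
      dplyr::summarise(
        ioam = mean(.data$ioam, na.rm = TRUE),
        dice = mean((.data$dice_lung + .data$dice_heart) / 2),
        iou = mean((.data$iou_lung + .data$iou_heart) / 2),
        n = dplyr::n(), .groups = "drop"
      )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(metrics, file.path(out_dir, "evaluation.csv"))
    if (!is.null(sal)) {
      readr::write_csv(sal, file.path(out_dir, "saliency_agreement.csv"))
    }
  }
  list(metrics = metrics, saliency = sal)
}
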