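# Synthetic chest-radiograph phantoms with known anatomy and pathology.
#
# Anatomy model: the thorax is one large ellipse, the lungs two dark
# ellipses, the heart a brighter mediastinal ellipse overlapping the left
# lung field (lung pixels under the heart are excluded from the lung mask, so
# heart and lung masks are disjoint by construction). Each pathology class
# maps to exactly one additive signature family:
#
#   Atelectasis        band opacity along the cardiac border of the left lung
#   Cardiomegaly       enlarged heart ellipse (mask edit; area ratio raised)
#   Consolidation      single large lobar blob opacity
#   Edema              diffuse basal + perihilar opacity
#   Effusion           dense opacity in the basal lung rows
#   Emphysema          global lucency (darkening) of both lung fields
#   Fibrosis           streaky horizontal bands in the lower lungs
#   Hernia             focal blob at the diaphragmatic dome below the lungs
#   Infiltration       diffuse multi-blob field across the lungs
#   Mass               one large focal nodular blob
#   Nodule             several small focal blobs
#   Pneumonia          patchy mid-lung multi-blob opacity
#   Pleural Thickening bright rim along the lateral lung margin
#   Pneumothorax       apical lucency with a sharp horizontal edge
#
# Images are gray arrays in [0, 255]; all randomness for study i derives from
# a per-study stream seeded by (seed, i), so cohorts are order-independent.

#' Phantom specification
#'
#' @param image_size Square image size in pixels; at least 32 and divisible
#'   by the transformer patch size in use (16).
#' @param prevalence Numeric vector of 14 per-class probabilities in
#'   `[0, 1]` (recycled if scalar) used by [generate_cohort()].
#' @param noise_sd Pixel noise standard deviation in gray levels.
#' @param lesion_intensity Additive gray-level offset of pathology
#'   signatures.
#' @param cardio_ratio Target heart/thorax area ratio for the enlarged heart
#'   (normal hearts sit near `normal_ratio`).
#' @param normal_ratio Heart/thorax area ratio of a normal heart.
#' @param seed Integer seed; every study derives its own RNG stream from it.
#' @return A list of class `cxr_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128L, prevalence = 0.15, noise_sd = 8,
                         lesion_intensity = 60, cardio_ratio = 0.55,
                         normal_ratio = 0.32, seed = 1L) {
  if (length(prevalence) == 1L) prevalence <- rep(prevalence, cxr_n_classes())
  if (length(prevalence) != cxr_n_classes()) {
    abort("prevalence must have length 1 or 14")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    abort("prevalence entries must lie in [0, 1]")
  }
  if (image_size < 32L || image_size %% 16L != 0L) {
    abort("image_size must be >= 32 and divisible by the patch size (16)")
  }
  structure(
    list(
      image_size = as.integer(image_size), prevalence = prevalence,
      noise_sd = noise_sd, lesion_intensity = lesion_intensity,
      cardio_ratio = cardio_ratio, normal_ratio = normal_ratio,
      seed = as.integer(seed)
    ),
    class = "cxr_phantom_spec"
  )
}

# base anatomy masks for one study; heart axes scaled to hit a target
# heart/thorax area ratio
phantom_anatomy <- function(s, cardiomegaly = FALSE) {
  n <- s$image_size
  cy <- n * 0.52
  cx <- n * 0.5
  thorax <- ellipse_mask(n, n, cy, cx, n * 0.42, n * 0.38)
  lung_l <- ellipse_mask(n, n, cy - n * 0.02, n * 0.345, n * 0.33, n * 0.16)
  lung_r <- ellipse_mask(n, n, cy - n * 0.02, n * 0.655, n * 0.33, n * 0.16)
  target <- if (cardiomegaly) s$cardio_ratio else s$normal_ratio
  # base heart axes (0.21 n, 0.155 n) against thorax (0.42 n, 0.38 n) give an
  # area ratio of 0.204; scale the axes to reach the requested ratio
  scale <- sqrt(target / 0.204)
  ry <- n * 0.21 * scale
  rx <- n * 0.155 * scale
  heart <- ellipse_mask(n, n, cy + n * 0.07, cx + n * 0.045, ry, rx) & thorax
  lungs <- (lung_l | lung_r) & thorax & !heart
  list(
    thorax = thorax, heart = heart, lung = lungs,
    lung_left = lung_l & thorax & !heart, lung_right = lung_r & thorax & !heart
  )
}

# add a soft gaussian blob to a field
add_blob <- function(field, cy, cx, sigma, amp) {
  h <- nrow(field)
  w <- ncol(field)
  y <- matrix(seq_len(h), h, w)
  x <- matrix(seq_len(w), h, w, byrow = TRUE)
  field + amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
}

# random point inside a mask
mask_point <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  pts[sample.int(nrow(pts), 1L), ]
}

#' Generate a single phantom study
#'
#' Renders the anatomy, injects one signature per positive label, adds pixel
#' noise and clips to `[0, 255]`. Deterministic for fixed `(spec$seed,
#' labels, index)`.
#'
#' @param spec A [phantom_spec()].
#' @param labels Optional binary 14-vector; drawn from `spec$prevalence`
#'   when missing.
#' @param index Study index within a cohort; combined with the seed for the
#'   per-study RNG stream.
#' @return A list of class `cxr_phantom_study` with `image` (gray matrix in
#'   `[0, 255]`), binary masks `lung_mask`, `heart_mask`, `thorax_mask`,
#'   `lung_left`, `lung_right`, the `labels` vector and a `lesions` tibble
#'   (class, center_y, center_x, extent).
#' @export
generate_phantom <- function(spec, labels = NULL, index = 1L) {
  stopifnot(inherits(spec, "cxr_phantom_spec"))
  set.seed(derive_seed(spec$seed, index))
  cls <- cxr_classes()
  if (is.null(labels)) {
    labels <- as.integer(runif(cxr_n_classes()) < spec$prevalence)
  }
  if (length(labels) != cxr_n_classes() || !is_binary(labels)) {
    abort("labels must be a binary vector of length 14")
  }
  labels <- as.integer(labels)
  names(labels) <- cls
  n <- spec$image_size
  anat <- phantom_anatomy(spec, cardiomegaly = labels[["Cardiomegaly"]] == 1L)

  img <- matrix(30, n, n)
  img[anat$thorax] <- 120
  img[anat$lung] <- 60
  img[anat$heart] <- 160
  amp <- spec$lesion_intensity
  lesions <- list()
  note <- function(class, cy, cx, extent) {
    lesions[[length(lesions) + 1L]] <<- tibble::tibble(
      class = class, center_y = cy, center_x = cx, extent = extent
    )
  }
  lung_rows <- range(which(rowSums(anat$lung) > 0))
  lung_h <- lung_rows[2] - lung_rows[1] + 1L
  basal_top <- lung_rows[2] - floor(0.3 * lung_h) + 1L
  apex_bot <- lung_rows[1] + floor(0.2 * lung_h) - 1L
  basal <- anat$lung
  basal[seq_len(basal_top - 1L), ] <- FALSE
  apex <- anat$lung
  if (apex_bot < n) apex[(apex_bot + 1L):n, ] <- FALSE

  field <- matrix(0, n, n)
  for (c_i in seq_along(cls)) {
    if (labels[c_i] == 0L) next
    cl <- cls[c_i]
    if (cl == "Cardiomegaly") {
      note(cl, n * 0.59, n * 0.545, sum(anat$heart))
      next
    }
    f <- matrix(0, n, n)
    if (cl == "Effusion") {
      f[basal] <- amp
      note(cl, mean(which(basal, arr.ind = TRUE)[, 1]), n / 2, sum(basal))
    } else if (cl == "Edema") {
      f[basal] <- amp * 0.7
      f <- add_blob(f, n * 0.5, n * 0.5, n * 0.12, amp * 0.5)
      note(cl, n * 0.55, n / 2, sum(basal))
    } else if (cl == "Pneumothorax") {
      f[apex] <- -amp
      note(cl, mean(which(apex, arr.ind = TRUE)[, 1]), n / 2, sum(apex))
    } else if (cl == "Emphysema") {
      f[anat$lung] <- -amp * 0.6
      note(cl, n / 2, n / 2, sum(anat$lung))
    } else if (cl == "Mass") {
      p <- mask_point(anat$lung)
      f <- add_blob(f, p[1], p[2], n * 0.07, amp * 1.3)
      note(cl, p[1], p[2], n * 0.07)
    } else if (cl == "Nodule") {
      for (i in 1:3) {
        p <- mask_point(anat$lung)
        f <- add_blob(f, p[1], p[2], n * 0.025, amp * 1.2)
        note(cl, p[1], p[2], n * 0.025)
      }
    } else if (cl == "Consolidation") {
      p <- mask_point(anat$lung)
      f <- add_blob(f, p[1], p[2], n * 0.11, amp)
      note(cl, p[1], p[2], n * 0.11)
    } else if (cl == "Infiltration") {
      for (i in 1:6) {
        p <- mask_point(anat$lung)
        f <- add_blob(f, p[1], p[2], n * 0.05, amp * 0.5)
      }
      note(cl, n / 2, n / 2, sum(anat$lung))
    } else if (cl == "Pneumonia") {
      mid <- anat$lung & !basal & !apex
      for (i in 1:4) {
        p <- mask_point(mid)
        f <- add_blob(f, p[1], p[2], n * 0.045, amp * 0.8)
      }
      note(cl, n / 2, n / 2, sum(mid))
    } else if (cl == "Atelectasis") {
      side <- anat$lung_left
      cols <- which(colSums(side) > 0)
      band <- side
      band[, setdiff(seq_len(n), tail(cols, ceiling(length(cols) * 0.4)))] <- FALSE
      f[band] <- amp * 0.9
      note(cl, n / 2, mean(tail(cols, 3)), sum(band))
    } else if (cl == "Fibrosis") {
      rows <- which(rowSums(basal) > 0)
      stripe <- rows[seq(1L, length(rows), by = 3L)]
      fb <- basal
      fb[setdiff(seq_len(n), stripe), ] <- FALSE
      f[fb] <- amp * 0.9
      note(cl, mean(stripe), n / 2, sum(fb))
    } else if (cl == "Pleural Thickening") {
      edge <- anat$lung & !ellipse_mask(n, n, n * 0.50, n * 0.5,
                                        n * 0.30, n * 0.30)
      f[edge] <- amp * 0.8
      note(cl, n / 2, n / 2, sum(edge))
    } else if (cl == "Hernia") {
      f <- add_blob(f, min(lung_rows[2] + n * 0.06, n - 2), n * 0.45,
                    n * 0.05, amp * 1.2)
      note(cl, lung_rows[2] + n * 0.06, n * 0.45, n * 0.05)
    }
    field <- field + f
  }
  img <- img + field
  img <- img + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
  img <- clamp(img, 0, 255)
  lesions <- if (length(lesions)) dplyr::bind_rows(lesions) else
    tibble::tibble(class = character(), center_y = numeric(),
                   center_x = numeric(), extent = numeric())
  structure(
    list(
      image = img,
      lung_mask = anat$lung * 1, heart_mask = anat$heart * 1,
      thorax_mask = anat$thorax * 1,
      lung_left = anat$lung_left * 1, lung_right = anat$lung_right * 1,
      labels = labels, lesions = lesions, index = as.integer(index)
    ),
    class = "cxr_phantom_study"
  )
}

#' Generate a cohort of phantom studies
#'
#' Labels are drawn independently per class with the spec prevalence; each
#' study uses its own RNG stream derived from `(spec$seed, index)`, so the
#' cohort is reproducible and order-independent.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of studies (>= 1).
#' @return A list of `cxr_phantom_study` objects.
#' @export
generate_cohort <- function(spec, n) {
  if (n < 1L) abort("n must be >= 1")
  lapply(seq_len(n), function(i) generate_phantom(spec, index = i))
}

#' Label matrix of a cohort
#'
#' @param cohort A list of `cxr_phantom_study`.
#' @return A tibble with `study` plus one 0/1 column per class.
#' @export
cohort_labels <- function(cohort) {
  m <- do.call(rbind, lapply(cohort, `[[`, "labels"))
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(study = seq_along(cohort)), out)
}

#' Write a cohort to disk
#'
#' Writes one grayscale PNG per image, three mask PNGs per study (lung,
#' heart, thorax), a single `labels.csv` (one row per study, 14 columns in
#' canonical class order) and a JSON manifest listing all files.
#'
#' @param cohort List of `cxr_phantom_study`.
#' @param directory Output directory (created if needed).
#' @return The manifest path, invisibly a list with all paths as attribute.
#' @export
write_cohort <- function(cohort, directory) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) abort("directory is not writable")
  paths <- purrr::map(seq_along(cohort), function(i) {
    st <- cohort[[i]]
    base <- sprintf("study%04d", i)
    img <- file.path(directory, paste0(base, ".png"))
    png::writePNG(st$image / 255, img)
    masks <- purrr::imap_chr(
      list(lung = st$lung_mask, heart = st$heart_mask, thorax = st$thorax_mask),
      function(m, nm) {
        p <- file.path(directory, paste0(base, "_", nm, ".png"))
        png::writePNG(m, p)
        p
      }
    )
    list(image = img, masks = as.list(masks))
  })
  lab <- cohort_labels(cohort)
  lab_path <- file.path(directory, "labels.csv")
  readr::write_csv(lab[, cxr_classes()], lab_path)
  manifest <- list(
    n = length(cohort),
    image_size = nrow(cohort[[1]]$image),
    classes = cxr_classes(),
    labels = "labels.csv",
    studies = purrr::map(paths, function(p) {
      list(image = basename(p$image),
           masks = purrr::map(p$masks, basename))
    })
  )
  man_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  man_path
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing `manifest.json`.
#' @return A list with `studies` (images + masks as matrices) and `labels`
#'   tibble.
#' @export
read_cohort <- function(directory) {
  man <- jsonlite::read_json(file.path(directory, "manifest.json"))
  labels <- readr::read_csv(file.path(directory, man$labels),
                            show_col_types = FALSE)
  studies <- purrr::map(man$studies, function(s) {
    img <- png::readPNG(file.path(directory, s$image)) * 255
    masks <- purrr::map(s$masks, function(m) {
      round(png::readPNG(file.path(directory, m)))
    })
    list(image = img, lung_mask = masks$lung, heart_mask = masks$heart,
         thorax_mask = masks$thorax)
  })
  list(studies = studies, labels = labels)
}
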