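# Grad-CAM saliency, anatomical alignment and region activation energies.
#
# Importance weights are the spatial means of d y_c / d A^k taken from the
# autodiff tape of a forward pass; the heatmap is ReLU of the weighted sum of
# feature maps, bilinearly upsampled to input resolution. Alignment is an
# exact elementwise product with a binary anatomy mask; normalization to
# [0, 1] divides by the map maximum (after alignment) and leaves all-zero
# maps untouched.

#' Grad-CAM heatmap for one class
#'
#' Runs the model on a single standardized image, backpropagates the class
#' logit to the retained backbone feature maps, pools the gradients spatially
#' into per-map weights, and forms `ReLU(sum_k alpha_k A^k)` upsampled to the
#' input resolution.
#'
#' @param model A `cxr_model`.
#' @param image Standardized `H x H x 3` array.
#' @param class_index Class index in 1..classes, or a class name.
#' @return A list of class `cxr_gradcam` with `heatmap` (H x H,
#'   non-negative), `heatmap_raw` (backbone resolution), `weights` (alpha_k),
#'   `class_index`, plus the model `probabilities`.
#' @export
grad_cam <- function(model, image, class_index) {
  if (is.character(class_index)) {
    class_index <- match(class_index, cxr_classes())
  }
  n_cls <- model$config$classes
  if (is.na(class_index) || class_index < 1L || class_index > n_cls) {
    abort("class index out of range")
  }
  x_rows <- batch_to_rows(list(image))
  fw <- model_forward_tape(model, x_rows, 1L, training = FALSE)
  seed <- matrix(0, 1, n_cls)
  seed[1, class_index] <- 1
  ad_backward(fw$tape, fw$logits, seed)
  g <- ad_grad(fw$feat) # (hs*hs) x K
  alpha <- colMeans(g) # Z = hs*hs spatial positions
  hm_small <- pmax(fw$feat$value %*% alpha, 0)
  hs <- fw$hs
  H <- model$config$image_size
  heat <- resize_bilinear(rows_to_mat(hm_small, hs, hs), H, H)
  heat <- pmax(heat, 0) # bilinear cannot undershoot, kept as a guard
  structure(
    list(
      heatmap = heat, heatmap_raw = rows_to_mat(hm_small, hs, hs),
      weights = alpha, class_index = class_index,
      probabilities = logistic(as.numeric(fw$logits$value))
    ),
    class = "cxr_gradcam"
  )
}

#' Constrain a heatmap to an anatomical mask
#'
#' Exact elementwise product; the mask is resized to the heatmap resolution
#' with nearest-neighbour interpolation if shapes differ. An empty mask
#' yields an all-zero map.
#'
#' @param heatmap Numeric matrix.
#' @param mask Binary matrix.
#' @return Matrix of the heatmap's shape.
#' @export
align <- function(heatmap, mask) {
  if (!all(dim(mask) == dim(heatmap))) {
    mask <- resize_nearest(mask, nrow(heatmap), ncol(heatmap))
  }
  heatmap * mask
}

#' Mean activation energy over a region
#'
#' `A_region = (1/|M_region|) * sum_ij L(i,j) M_region(i,j)`.
#'
#' @param aligned_map Numeric matrix (typically an aligned heatmap).
#' @param region_mask Binary matrix; must be nonempty.
#' @return Scalar energy (>= 0 for non-negative maps).
#' @export
region_energy <- function(aligned_map, region_mask) {
  if (!all(dim(region_mask) == dim(aligned_map))) {
    region_mask <- resize_nearest(region_mask, nrow(aligned_map), ncol(aligned_map))
  }
  npix <- sum(region_mask)
  if (npix == 0) abort("region mask is empty")
  sum(aligned_map * region_mask) / npix
}

#' Normalize a non-negative map to [0, 1]
#'
#' Division by the map maximum; an all-zero map is returned unchanged (no
#' NaN). Pixel rank order is preserved.
#'
#' @param heatmap Non-negative matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_map <- function(heatmap) {
  if (any(heatmap < 0)) abort("heatmap must be non-negative")
  m <- max(heatmap)
  if (m == 0) {
    return(heatmap)
  }
  heatmap / m
}

#' Geometric sub-regions of the anatomy masks
#'
#' Derives the named regions used by the reasoning layer from lung and heart
#' masks: `lung`, `heart`, `thorax`, `basal_lung` (lowest 30% of lung rows),
#' `apical_lung` (highest 20%), `costophrenic` (basal-lateral corners: basal
#' band intersected with the outer thirds of the lung columns), `mid_lung`,
#' and `lateral_lung` (outer column thirds).
#'
#' @param lung_mask,heart_mask,thorax_mask Binary matrices of equal shape.
#' @return Named list of binary matrices.
#' @export
anatomy_regions <- function(lung_mask, heart_mask, thorax_mask) {
  stopifnot(all(dim(lung_mask) == dim(heart_mask)),
            all(dim(lung_mask) == dim(thorax_mask)))
  n <- nrow(lung_mask)
  rows_present <- which(rowSums(lung_mask) > 0)
  if (length(rows_present) == 0) abort("lung mask is empty")
  top <- min(rows_present)
  bot <- max(rows_present)
  lh <- bot - top + 1L
  basal <- lung_mask
  basal_top <- bot - floor(0.3 * lh) + 1L
  if (basal_top > 1L) basal[seq_len(basal_top - 1L), ] <- 0
  apical <- lung_mask
  apex_bot <- top + floor(0.2 * lh) - 1L
  if (apex_bot < n) apical[(apex_bot + 1L):n, ] <- 0
  mid <- lung_mask * (1 - basal) * (1 - apical)
  cols_present <- which(colSums(lung_mask) > 0)
  cl <- range(cols_present)
  cw <- cl[2] - cl[1] + 1L
  lateral <- lung_mask
  inner <- (cl[1] + floor(cw / 3)):(cl[2] - floor(cw / 3))
  lateral[, inner] <- 0
  costo <- basal * lateral
  list(
    lung = lung_mask, heart = heart_mask, thorax = thorax_mask,
    basal_lung = basal, apical_lung = apical, mid_lung = mid,
    lateral_lung = lateral, costophrenic = costo
  )
}

#' Aligned saliency with per-region energies
#'
#' Aligns a Grad-CAM heatmap with the thoracic anatomy (lung union heart),
#' normalizes it to `[0, 1]`, and computes the mean activation energy in
#' each derived region.
#'
#' @param gradcam A `cxr_gradcam` (or bare heatmap matrix).
#' @param lung_mask,heart_mask,thorax_mask Binary anatomy masks.
#' @return A list of class `cxr_aligned_saliency` with `aligned_map`
#'   (normalized), `region_energies` (tibble region/energy), `regions`, and
#'   `class_index` when available.
#' @export
align_saliency <- function(gradcam, lung_mask, heart_mask, thorax_mask) {
  heat <- if (inherits(gradcam, "cxr_gradcam")) gradcam$heatmap else gradcam
  regions <- anatomy_regions(lung_mask, heart_mask, thorax_mask)
  anatomy <- 1 * ((lung_mask + heart_mask) > 0)
  aligned <- normalize_map(align(heat, anatomy))
  energies <- tibble::tibble(
    region = names(regions),
    energy = vapply(regions, function(m) {
      if (sum(m) == 0) 0 else region_energy(aligned, m)
    }, numeric(1))
  )
  structure(
    list(
      aligned_map = aligned, region_energies = energies, regions = regions,
      anatomy_mask = anatomy,
      class_index = if (inherits(gradcam, "cxr_gradcam")) gradcam$class_index
      else NA_integer_
    ),
    class = "cxr_aligned_saliency"
  )
}
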