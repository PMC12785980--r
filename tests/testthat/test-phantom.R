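test_that("an all-negative label vector yields a lesion-free study", {
  st <- generate_phantom(tiny_spec(), labels = rep(0L, 14))
  expect_equal(nrow(st$lesions), 0L)
  expect_true(all(st$labels == 0L))
  expect_true(all(st$image >= 0 & st$image <= 255))
})

test_that("generation is deterministic for a fixed seed and labels", {
  lab <- c(1L, 0L, 0L, 1L, 0L, rep(0L, 9))
  a <- generate_phantom(tiny_spec(seed = 9L), labels = lab, index = 3L)
  b <- generate_phantom(tiny_spec(seed = 9L), labels = lab, index = 3L)
  expect_identical(a$image, b$image)
  expect_identical(a$lung_mask, b$lung_mask)
  d <- generate_phantom(tiny_spec(seed = 10L), labels = lab, index = 3L)
  expect_false(identical(a$image, d$image))
})

test_that("cardiomegaly enlarges the heart mask past the configured ratio", {
  lab_pos <- as.integer(cxr_classes() == "Cardiomegaly")
  pos <- generate_phantom(tiny_spec(), labels = lab_pos)
  neg <- generate_phantom(tiny_spec(), labels = rep(0L, 14))
  # brute-force pixel counts
  r_pos <- sum(pos$heart_mask == 1) / sum(pos$thorax_mask == 1)
  r_neg <- sum(neg$heart_mask == 1) / sum(neg$thorax_mask == 1)
  expect_gt(sum(pos$heart_mask), sum(neg$heart_mask))
  expect_gt(r_pos, 0.5)
  expect_lt(r_neg, 0.5)
})

test_that("masks obey the geometry contract", {
  set.seed(4)
  for (i in 1:5) {
    st <- generate_phantom(tiny_spec(seed = 20L + i))
    expect_true(all(st$heart_mask <= st$thorax_mask))
    expect_true(all(st$lung_mask <= st$thorax_mask))
    overlap <- sum(st$lung_mask * st$heart_mask)
    expect_lt(overlap / max(1, sum((st$lung_mask + st$heart_mask) > 0)), 0.2)
    expect_equal(dim(st$image), dim(st$lung_mask))
    # labels consistent with injected lesions
    for (cl in cxr_classes()) {
      has_lesion <- cl %in% st$lesions$class
      expect_identical(unname(st$labels[cl] == 1L), has_lesion)
    }
  }
})

test_that("degenerate prevalences produce constant label vectors", {
  lab0 <- cohort_labels(generate_cohort(tiny_spec(prevalence = 0), 10))
  expect_true(all(lab0[, cxr_classes()] == 0))
  lab1 <- cohort_labels(generate_cohort(tiny_spec(prevalence = 1), 5))
  expect_true(all(lab1[, cxr_classes()] == 1))
})

test_that("cohort label frequencies converge to the prevalence", {
  n <- 2000L
  cohort <- generate_cohort(tiny_spec(prevalence = 0.5, seed = 123L,
                                      noise_sd = 0), n)
  lab <- as.matrix(cohort_labels(cohort)[, cxr_classes()])
  se <- sqrt(0.5 * 0.5 / n)
  freq <- colMeans(lab)
  expect_true(all(abs(freq - 0.5) <= 3 * se))
})

test_that("invalid specs and labels are rejected", {
  expect_error(phantom_spec(prevalence = 1.2), "prevalence")
  expect_error(phantom_spec(image_size = 20), "image_size")
  expect_error(generate_phantom(tiny_spec(), labels = c(1, 0)), "length 14")
  expect_error(generate_phantom(tiny_spec(), labels = rep(2, 14)), "binary")
  expect_error(generate_cohort(tiny_spec(), 0), ">= 1")
})

test_that("write_cohort emits the expected files and round-trips", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(tiny_spec(prevalence = 0.3, seed = 5L), 3)
  man <- write_cohort(cohort, dir)
  expect_true(file.exists(man))
  expect_length(list.files(dir, pattern = "^study\\d+\\.png$"), 3L)
  expect_length(list.files(dir, pattern = "_(lung|heart|thorax)\\.png$"), 9L)
  lab <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  expect_equal(nrow(lab), 3L)
  expect_identical(names(lab), cxr_classes())
  # lossless round trip of labels and masks
  back <- read_cohort(dir)
  orig <- as.matrix(cohort_labels(cohort)[, cxr_classes()])
  expect_equal(unname(as.matrix(back$labels)), unname(orig))
  for (i in 1:3) {
    expect_equal(back$studies[[i]]$lung_mask, unname(cohort[[i]]$lung_mask))
    expect_equal(back$studies[[i]]$heart_mask, unname(cohort[[i]]$heart_mask))
    expect_equal(back$studies[[i]]$thorax_mask, unname(cohort[[i]]$thorax_mask))
  }
})
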