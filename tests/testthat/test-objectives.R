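test_that("BCE with logits reproduces hand-computed values", {
  expect_equal(bce_multilabel(rep(0, 14), rbinom(14, 1, 0.5)), log(2),
               tolerance = 1e-12)
  big <- 50
  z <- c(big, -big)
  expect_lt(bce_multilabel(z, c(1, 0)), 1e-20)
  # z = (1, -1), y = (1, 0): both terms are -log sigmoid(1)
  expect_equal(bce_multilabel(c(1, -1), c(1, 0)), -log(1 / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_error(bce_multilabel(c(0, 0), c(0.3, 1)), "binary")
})

test_that("class-balanced focal loss has the published limits and values", {
  set.seed(1)
  p <- matrix(runif(28, 0.05, 0.95), 2, 14)
  y <- matrix(rbinom(28, 1, 0.5), 2, 14)
  # gamma = 0, unit alpha reduces to plain cross-entropy
  ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(class_balanced_focal(p, y, focal_params(gamma = 0)), ce,
               tolerance = 1e-12)
  # p_t = 1 - eps everywhere drives the loss to ~0
  expect_lt(class_balanced_focal(matrix(1 - 1e-12, 1, 14),
                                 matrix(1, 1, 14), focal_params()), 1e-10)
  # single sample, gamma = 2, p_t = 0.9
  expect_equal(class_balanced_focal(matrix(0.9), matrix(1), focal_params(gamma = 2,
                                    alpha = 1)),
               0.01 * (-log(0.9)), tolerance = 1e-12)
  expect_error(class_balanced_focal(matrix(1.0), matrix(1), focal_params()),
               "strictly")
})

test_that("effective-number weights are normalized and favour rare classes", {
  fp <- focal_params(class_counts = c(10, rep(10000, 13)))
  expect_equal(mean(fp$alpha), 1, tolerance = 1e-12)
  expect_gt(fp$alpha[1], fp$alpha[2])
})

test_that("focal loss is monotone in p_t and gamma damps easy examples", {
  grid <- seq(0.05, 0.95, by = 0.05)
  l <- vapply(grid, function(p) {
    class_balanced_focal(matrix(p), matrix(1), focal_params(gamma = 2, alpha = 1))
  }, numeric(1))
  expect_true(all(diff(l) < 0))
  easy <- grid[grid > 0.5]
  l0 <- vapply(easy, function(p) {
    class_balanced_focal(matrix(p), matrix(1), focal_params(gamma = 0, alpha = 1))
  }, numeric(1))
  l2 <- vapply(easy, function(p) {
    class_balanced_focal(matrix(p), matrix(1), focal_params(gamma = 2, alpha = 1))
  }, numeric(1))
  expect_true(all(l2 / l0 < 0.25)) # (1 - p_t)^2 < 0.25 for p_t > 0.5
})

test_that("dice loss hits its closed-form anchors", {
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_lt(dice_loss(m, m), 1e-6)
  a <- matrix(0, 4, 4)
  a[1:2, ] <- 1
  b <- 1 - a
  expect_equal(dice_loss(a, b), 1, tolerance = 1e-6)
  # |M| = 2, |Mhat| = 2, overlap 1 -> 1 - 2/4
  mm <- matrix(0, 2, 2)
  mm[1, ] <- 1
  hh <- matrix(0, 2, 2)
  hh[, 1] <- 1
  expect_equal(dice_loss(hh, mm), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "binary")
})

test_that("dice loss is symmetric and translation invariant on binary pairs", {
  set.seed(8)
  a <- matrix(rbinom(100, 1, 0.4), 10, 10)
  b <- matrix(rbinom(100, 1, 0.4), 10, 10)
  expect_equal(dice_loss(a, b), dice_loss(b, a), tolerance = 1e-12)
  shift <- function(m) rbind(m[-1, ], 0)
  expect_equal(dice_loss(shift(a), shift(b)),
               dice_loss(a, b), tolerance = 0.06) # edge rows leave the frame
})

test_that("the joint objective is an exact weighted sum", {
  expect_equal(joint_loss(0.3, 0.2, 0), 0.3)
  expect_equal(joint_loss(0.3, 0.2, 1), 0.5)
  expect_equal(joint_loss(1.5, 2, 0.25), 2)
  expect_error(joint_loss(1, 1, -1))
})

test_that("threshold selection maximizes per-class accuracy with smallest-tau ties", {
  p <- matrix(c(0.9, 0.8, 0.1, 0.2), 4, 1)
  y <- matrix(c(1, 1, 0, 0), 4, 1)
  thr <- select_thresholds(p, y, grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(thr$tau, 0.25)
  expect_equal(thr$accuracy, 1)
  # degenerate single-class column falls back to the smallest grid value
  thr2 <- select_thresholds(matrix(runif(4)), matrix(1, 4, 1))
  expect_equal(thr2$tau, 0.05)
  # returned tau attains the maximum accuracy, exhaustively
  set.seed(10)
  p3 <- matrix(runif(60), 20, 3)
  y3 <- matrix(rbinom(60, 1, 0.5), 20, 3)
  grid <- seq(0.05, 0.95, by = 0.01)
  thr3 <- select_thresholds(p3, y3, grid)
  for (c_i in 1:3) {
    accs <- vapply(grid, function(t) mean((p3[, c_i] >= t) == y3[, c_i]),
                   numeric(1))
    expect_equal(thr3$accuracy[c_i], max(accs))
    expect_equal(thr3$tau[c_i], grid[which.max(accs)])
  }
  expect_error(select_thresholds(matrix(0, 0, 1), matrix(0, 0, 1)), "empty")
})

test_that("binarize is inclusive at the threshold and matches a loop oracle", {
  p <- matrix(c(0.5, 0.49), 1, 2)
  out <- binarize(p, c(0.5, 0.5))
  expect_identical(as.integer(out), c(1L, 0L))
  expect_true(all(binarize(matrix(0, 3, 2), c(0.1, 0.9)) == 0))
  set.seed(11)
  pm <- matrix(runif(50 * 14), 50, 14)
  tau <- runif(14, 0.2, 0.8)
  got <- binarize(pm, tau)
  ref <- matrix(0L, 50, 14)
  for (i in 1:50) for (j in 1:14) ref[i, j] <- as.integer(pm[i, j] >= tau[j])
  expect_identical(unname(got), ref)
})

test_that("thresholds round-trip through JSON", {
  thr <- select_thresholds(matrix(runif(28), 2, 14),
                           matrix(rbinom(28, 1, 0.5), 2, 14))
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back$tau, thr$tau)
  expect_equal(back$class, thr$class)
})
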