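test_that("Dice handles identity, disjoint, partial overlap and empty masks", {
  a <- seg_mask(matrix(c(1, 1, 1, 1, 0, 0), 2, 3) == 1)
  expect_equal(dsc(a, a), 1)
  b <- seg_mask(matrix(c(0, 0, 0, 0, 1, 1), 2, 3) == 1)
  expect_equal(dsc(a, b), 0)
  # |A| = 4, |B| = 4, |A n B| = 2 -> 2*2/(4+4) = 0.5
  c1 <- seg_mask(matrix(c(1, 1, 0, 0, 1, 1), 2, 3) == 1)
  expect_equal(dsc(a, c1), 0.5)
  e <- seg_mask(matrix(0L, 2, 3))
  expect_equal(dsc(e, e), 1)   # both empty: perfect agreement by convention
  expect_equal(dsc(a, e), 0)   # one empty
  expect_equal(dsc(a, c1), dsc(c1, a))
  expect_error(dsc(a, seg_mask(matrix(0L, 3, 3))), "shape")
})

test_that("the Dice matrix has one entry per unordered pair, all in [0, 1]", {
  set.seed(5)
  cs <- build_candidates(named_mask_set(6))
  dm <- dsc_matrix(cs)
  expect_length(dm$values, 66)           # 12 * 11 / 2
  expect_length(dm$candidate_ids, 12)
  expect_true(all(dm$values >= 0 & dm$values <= 1))
  lite <- dsc_matrix(cs, pool = "singles")
  expect_length(lite$values, 15)         # 6 * 5 / 2
})

test_that("Dice matrix values are invariant to candidate input order", {
  set.seed(6)
  masks <- named_mask_set(5)
  dm1 <- dsc_matrix(masks)
  perm <- masks[c(3, 1, 5, 2, 4)]
  dm2 <- dsc_matrix(perm)
  for (key in dm1$feature_order) {
    ids <- strsplit(key, "--", fixed = TRUE)[[1]]
    k2 <- if (key %in% dm2$feature_order) key else paste(ids[2], ids[1], sep = "--")
    expect_equal(unname(dm1$values[key]), unname(dm2$values[k2]))
  }
})

test_that("identical candidates give an all-ones matrix", {
  m <- random_mask_set(1, p = 0.5)[[1]]
  masks <- stats::setNames(rep(list(m), 4), paste0("m", 1:4))
  expect_true(all(dsc_matrix(masks)$values == 1))
})

test_that("regression recovers an exact linear target to 1e-8", {
  set.seed(17)
  matrices <- lapply(1:20, function(i) dsc_matrix(named_mask_set(3, p = 0.5)))
  X <- do.call(rbind, lapply(matrices, function(m) unname(m$values)))
  alpha_true <- 0.2
  beta_true <- c(0.3, -0.1, 0.25)
  y <- alpha_true + X %*% beta_true
  stopifnot(all(y >= 0 & y <= 1))
  obs <- cbind(model1 = as.vector(y))
  qp <- fit_quality_predictors(matrices, obs)$model1
  expect_equal(qp$alpha, alpha_true, tolerance = 1e-8)
  expect_equal(unname(qp$betas), beta_true, tolerance = 1e-8)
  # and predictions reproduce the targets exactly
  preds <- vapply(matrices, function(m) predict_dsc(qp, m), numeric(1))
  expect_equal(preds, as.vector(y), tolerance = 1e-8)
})

test_that("fitted predictions agree with an independent normal-equations oracle", {
  set.seed(18)
  matrices <- lapply(1:40, function(i) dsc_matrix(named_mask_set(4, p = 0.5)))
  X <- do.call(rbind, lapply(matrices, function(m) unname(m$values)))
  y <- pmin(pmax(0.5 + 0.2 * X[, 1] - 0.1 * X[, 4] +
                   rnorm(40, 0, 0.02), 0), 1)
  qp <- fit_quality_predictors(matrices, cbind(m = y))$m
  # oracle: solve the normal equations of [1, X] directly
  D <- cbind(1, X)
  coef <- solve(crossprod(D), crossprod(D, y))
  fitted_mine <- qp$alpha + X %*% qp$betas
  fitted_oracle <- D %*% coef
  expect_lt(max(abs(fitted_mine - fitted_oracle)), 1e-8)
  expect_equal(qp$alpha, coef[1], tolerance = 1e-6)
})

test_that("constant targets give alpha = c and zero weights", {
  set.seed(19)
  matrices <- lapply(1:10, function(i) dsc_matrix(named_mask_set(3)))
  qp <- suppressWarnings(
    fit_quality_predictors(matrices, cbind(m = rep(0.42, 10))))$m
  expect_equal(qp$alpha, 0.42, tolerance = 1e-10)
  expect_equal(max(abs(qp$betas)), 0, tolerance = 1e-10)
})

test_that("prediction applies the linear form, clipping, and order checks", {
  fo <- c("a--b", "a--c")
  qp <- structure(list(model_id = "a", alpha = 0.1,
                       betas = stats::setNames(c(0.4, 0.5), fo),
                       feature_order = fo), class = "quality_predictor")
  dm <- structure(list(values = stats::setNames(c(0.5, 0.8), fo),
                       feature_order = fo, candidate_ids = c("a", "b", "c")),
                  class = "dsc_matrix")
  expect_equal(predict_dsc(qp, dm), 0.1 + 0.4 * 0.5 + 0.5 * 0.8) # 0.7

  qp0 <- qp; qp0$betas[] <- 0; qp0$alpha <- 0.3
  expect_equal(predict_dsc(qp0, dm), 0.3)   # intercept-only
  qp2 <- qp0; qp2$alpha <- 2
  expect_equal(predict_dsc(qp2, dm), 1)     # clipped at the ceiling
  qpn <- qp0; qpn$alpha <- -1
  expect_equal(predict_dsc(qpn, dm), 0)     # clipped at the floor

  dm_bad <- dm; dm_bad$feature_order <- rev(dm$feature_order)
  expect_error(predict_dsc(qp, dm_bad), "feature order")
})

test_that("predictors round-trip through JSON", {
  set.seed(20)
  matrices <- lapply(1:12, function(i) dsc_matrix(named_mask_set(3)))
  obs <- cbind(model1 = runif(12, 0.3, 0.9), model2 = runif(12, 0.3, 0.9))
  preds <- fit_quality_predictors(matrices, obs)
  f <- tempfile(fileext = ".json")
  write_predictors(preds, f)
  back <- read_predictors(f)
  expect_identical(names(back), names(preds))
  expect_equal(back$model2$alpha, preds$model2$alpha)
  expect_equal(back$model2$betas, preds$model2$betas)
  expect_equal(predict_dsc(back$model1, matrices[[1]]),
               predict_dsc(preds$model1, matrices[[1]]))
})

test_that("ensemble agreement correlates positively with selected quality", {
  # the premise behind quality scoring: less inter-candidate disagreement,
  # better segmentation. Construct noisy corruptions of a ground truth at
  # varying severity and check the association across images.
  set.seed(44)
  gt <- tiny_sample(1)$gt_mask
  flip <- function(m, k) {
    v <- as.vector(unclass(m))
    idx <- sample(length(v), k)
    v[idx] <- 1L - v[idx]
    seg_mask(matrix(v, nrow(m), ncol(m)))
  }
  mean_agree <- obs_best <- numeric(30)
  for (i in 1:30) {
    severity <- sample(c(5, 30, 80, 150), 1)
    masks <- stats::setNames(lapply(1:4, function(j) flip(gt, severity)),
                             paste0("m", 1:4))
    dm <- dsc_matrix(masks)
    mean_agree[i] <- mean(dm$values)
    obs_best[i] <- max(vapply(masks, dsc, numeric(1), b = gt))
  }
  expect_gt(cor(mean_agree, obs_best), 0)
})
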