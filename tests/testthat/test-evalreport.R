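test_that("confusion counts and rates follow the screening definitions", {
  # TP=2, FP=1, TN=3, FN=0 -> ACC 5/6, TPR 1, FPR 0.25
  observed <- c(0.8, 0.9, 0.5, 0.6, 0.65, 0.3)
  predicted <- c(0.75, 0.8, 0.72, 0.6, 0.6, 0.5)
  cq <- classify_quality(predicted, observed, threshold = 0.7)
  expect_identical(c(cq$tp, cq$fp, cq$tn, cq$fn), c(2L, 1L, 3L, 0L))
  expect_equal(cq$acc, 5 / 6)
  expect_equal(cq$tpr, 1)
  expect_equal(cq$fpr, 0.25)
  expect_identical(cq$tp + cq$fp + cq$tn + cq$fn, cq$n)
})

test_that("perfect predictions classify perfectly; degenerate denominators are NA", {
  obs <- c(0.9, 0.6, 0.8, 0.4)
  expect_equal(classify_quality(obs, obs)$acc, 1)
  allgood <- classify_quality(c(0.8, 0.9), c(0.75, 0.95))
  expect_equal(allgood$tpr, 1)
  expect_true(is.na(allgood$fpr))
  expect_error(classify_quality(1:3 / 4, 1:2 / 4), "equal length")
  expect_error(classify_quality(obs, obs, threshold = 1.2), "threshold")
})

test_that("prediction accuracy reports MAE and Pearson r with hand values", {
  id <- c(0.2, 0.5, 0.9)
  pa <- prediction_accuracy(id, id)
  expect_equal(pa$mae, 0)
  expect_equal(pa$r, 1)
  # (0,0), (0.5,1), (1,2): perfectly linear, MAE = mean(0, 0.5, 1) = 0.5
  pa2 <- prediction_accuracy(c(0, 0.5, 1), c(0, 1, 2))
  expect_equal(pa2$r, 1)
  expect_equal(pa2$mae, 0.5)
  expect_warning(pa3 <- prediction_accuracy(c(0.5, 0.5, 0.5), c(0, 1, 2)),
                 "zero variance")
  expect_true(is.na(pa3$r))
})

test_that("T1 estimation is the masked arithmetic mean", {
  uni <- t1_map(matrix(900, 4, 4))
  m <- seg_mask(matrix(c(1, 0, 0, 1, rep(0, 12)), 4, 4) == 1)
  expect_equal(t1_estimate(uni, m), 900)
  two <- t1_map(matrix(c(800, 1000, rep(0, 14)), 4, 4))
  m2 <- seg_mask(matrix(c(1, 1, rep(0, 14)), 4, 4) == 1)
  expect_equal(t1_estimate(two, m2), 900)
  expect_error(t1_estimate(uni, seg_mask(matrix(0L, 4, 4))), "empty mask")
})

test_that("zero-noise phantom recovers its myocardial T1 exactly", {
  sp <- phantom_spec(image_size = 48, endo_radius = 8, wall_thickness = 4,
                     tier = "excellent", noise_sd = 0, artefacts = character(),
                     seed = 2, t1_myocardium = 1234)
  s <- generate_phantom(sp)
  expect_equal(t1_estimate(s$t1_map, s$gt_mask), 1234, tolerance = 1e-9)
})

test_that("Bland-Altman uses pairwise-mean relative differences", {
  ident <- bland_altman(c(1000, 1100, 900), c(1000, 1100, 900))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$lower, ident$upper), c(0, 0))

  # pairs (1050, 1000), (950, 1000): rel diffs 100*50/1025, -100*50/975
  ba <- bland_altman(c(1050, 950, 1000), c(1000, 1000, 1000))
  expect_equal(ba$rel_diff[1], 100 * 50 / 1025)
  expect_equal(ba$rel_diff[2], -100 * 50 / 975)
  expect_equal(ba$bias, mean(ba$rel_diff))
  expect_true(ba$lower <= ba$bias && ba$bias <= ba$upper)

  # relative differences are scale invariant
  ba2 <- bland_altman(2 * c(1050, 950, 1000), 2 * c(1000, 1000, 1000))
  expect_equal(ba2$rel_diff, ba$rel_diff)

  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
  expect_error(bland_altman(c(1, -2, 3), c(1, 1, 1)), "non-positive")
})

test_that("T1 agreement combines absolute and relative statistics", {
  auto <- c(950, 960, 930, 980, 1010)
  manual <- c(955, 950, 940, 975, 1000)
  ag <- t1_agreement(auto, manual)
  expect_equal(ag$mean_error, mean(auto - manual))
  expect_equal(ag$mae, mean(abs(auto - manual)))
  expect_equal(ag$bland_altman$bias, mean(100 * (auto - manual) / ((auto + manual) / 2)))
  f <- tempfile(fileext = ".png")
  plot_bland_altman(ag$bland_altman, (auto + manual) / 2,
                    tier = c("a", "a", "b", "b", "a"), file = f)
  expect_true(file.exists(f))
})

test_that("range restriction shrinks r while MAE stays comparable", {
  # constructed illustration: accurate predictions over a wide pooled range
  # vs the narrow top slice that selection keeps
  set.seed(12)
  observed <- runif(400, 0.2, 0.95)
  predicted <- pmin(pmax(observed + rnorm(400, 0, 0.03), 0), 1)
  selected <- observed > 0.8
  rr <- range_restriction(predicted, observed, selected)
  expect_lt(rr$selected$r, rr$pooled$r)
  expect_lt(rr$selected$mae, rr$pooled$mae + 0.01)
  # no restriction: identical pairs
  rr_all <- range_restriction(predicted, observed, rep(TRUE, 400))
  expect_equal(rr_all$selected$r, rr_all$pooled$r)
  expect_error(range_restriction(predicted, observed, logical(400)), "empty")
  # size-2 subsets keep r defined as NA-free only with >= 3 pairs
  rr2 <- range_restriction(predicted, observed, c(1, 2))
  expect_true(is.na(rr2$selected$r))
})

test_that("the per-model report mirrors the summary-table structure", {
  set.seed(13)
  obs <- matrix(runif(40, 0.5, 0.95), 10, 4,
                dimnames = list(NULL, c("u7", "u11", "c1", "c2")))
  pred <- pmin(pmax(obs + rnorm(40, 0, 0.02), 0), 1)
  rep_tab <- qc_report(obs, pred)
  expect_identical(names(rep_tab),
                   c("model_id", "mean_dsc", "sd_dsc", "mae", "r", "p_value"))
  expect_identical(rep_tab$model_id, colnames(obs))
  expect_equal(rep_tab$mean_dsc[2], mean(obs[, 2]))
  expect_equal(rep_tab$mae[3], mean(abs(pred[, 3] - obs[, 3])))
})
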