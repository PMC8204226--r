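#' Good/poor segmentation classification from predicted Dice
#'
#' Dichotomizes observed and predicted Dice at a quality threshold
#' (default 0.7): a segmentation is "good" when its observed Dice is at or
#' above the threshold, and predicted-good when its predicted Dice is.
#' Counts follow the screening convention in which "positive" means
#' predicted-good: TP = observed good & predicted good, FP = observed poor
#' but predicted good, TN = observed poor & predicted poor, FN = observed
#' good but predicted poor. Reports accuracy `(TP+TN)/n`, true positive
#' rate `TP/(TP+FN)` and false positive rate `FP/(FP+TN)`; a degenerate
#' denominator yields `NA` rather than 0.
#'
#' @param predicted,observed numeric vectors of equal length (Dice values).
#' @param threshold quality threshold in (0, 1).
#' @return List with `tp`, `fp`, `tn`, `fn`, `acc`, `tpr`, `fpr`, `n`,
#'   `threshold`.
#' @export
classify_quality <- function(predicted, observed, threshold = 0.7) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  og <- observed >= threshold
  pg <- predicted >= threshold
  tp <- sum(og & pg); fp <- sum(!og & pg)
  tn <- sum(!og & !pg); fn <- sum(og & !pg)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       acc = (tp + tn) / length(observed),
       tpr = rate(tp, tp + fn),
       fpr = rate(fp, fp + tn),
       n = length(observed), threshold = threshold)
}

#' Accuracy of Dice prediction: MAE and Pearson correlation
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return List with `mae`, `r`, `p_value`, `n`. With fewer than 3 pairs or
#'   zero variance in either vector, `r` and `p_value` are `NA` (with a
#'   warning for the degenerate-variance case).
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length")
  }
  mae <- mean(abs(predicted - observed))
  r <- p <- NA_real_
  if (length(predicted) >= 3) {
    if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
      warning("zero variance in predicted or observed Dice; correlation undefined")
    } else {
      ct <- stats::cor.test(predicted, observed)
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
  }
  list(mae = mae, r = r, p_value = p, n = length(predicted))
}

#' Mean myocardial T1 over a segmentation
#'
#' The clinical endpoint: the arithmetic mean of the T1 values of all
#' pixels labeled myocardium.
#'
#' @param map a [t1_map()].
#' @param mask a [seg_mask()] aligned with `map`.
#' @return Scalar, milliseconds.
#' @export
t1_estimate <- function(map, mask) {
  check_same_shape(list(map, mask))
  if (sum(mask) == 0) {
    stop("empty mask: no myocardium found, cannot estimate T1")
  }
  mean(unclass(map)[as_mask_matrix(mask) == 1L])
}

#' Bland-Altman agreement of paired T1 estimates
#'
#' Expresses each pair as a relative difference in percent,
#' `100 * (auto - manual) / pairwise mean`, and reports the bias (mean
#' relative difference) and 95% limits of agreement (`bias +/- 1.96 * SD`).
#' Relative differences are scale-invariant, so both vectors may be in any
#' common unit.
#'
#' @param auto,manual numeric vectors of equal length (>= 3), strictly
#'   positive pairwise means.
#' @return List with `bias`, `lower`, `upper` (percent), `sd`, and
#'   `rel_diff` (per-case percentages).
#' @export
bland_altman <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("paired vectors must have equal length")
  if (length(auto) < 3) stop("need at least 3 pairs")
  denom <- (auto + manual) / 2
  if (any(denom <= 0)) stop("non-positive pairwise means; relative differences undefined")
  rel <- 100 * (auto - manual) / denom
  s <- stats::sd(rel)
  bias <- mean(rel)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd = s, rel_diff = rel)
}

#' T1 agreement report between automatic and manual segmentations
#'
#' Combines the absolute-scale statistics (mean error, mean absolute error,
#' Pearson r, all in ms) with the relative-scale Bland-Altman analysis.
#'
#' @param auto,manual numeric vectors of paired T1 estimates (ms).
#' @return List with `mean_error`, `mae`, `sd_error`, `r`, `p_value`, and
#'   `bland_altman` (see [bland_altman()]).
#' @export
t1_agreement <- function(auto, manual) {
  pa <- prediction_accuracy(auto, manual)
  err <- auto - manual
  list(mean_error = mean(err), mae = mean(abs(err)),
       sd_error = stats::sd(err), r = pa$r, p_value = pa$p_value,
       bland_altman = bland_altman(auto, manual))
}

#' Range-restriction comparison: pooled candidates vs QCD-selected outputs
#'
#' Pearson correlation between predicted and observed Dice shrinks when
#' the evaluated set is restricted to a narrow quality range - precisely
#' what QCD selection does by construction. This helper computes (r, MAE)
#' twice: over all candidate segmentations pooled across images, and over
#' the selected subset only, making the phenomenon directly inspectable:
#' the selected set typically shows a *lower* r at comparable or better
#' MAE, so a weak correlation alone does not indicate poor quality
#' prediction.
#'
#' @param predicted,observed numeric vectors over all pooled candidate
#'   segmentations.
#' @param selected logical or index vector marking the QCD-selected subset.
#' @return List with `pooled` and `selected`, each a [prediction_accuracy()]
#'   result.
#' @export
range_restriction <- function(predicted, observed, selected) {
  idx <- if (is.logical(selected)) which(selected) else as.integer(selected)
  if (length(idx) == 0) stop("selected subset is empty")
  list(pooled = prediction_accuracy(predicted, observed),
       selected = prediction_accuracy(predicted[idx], observed[idx]))
}

#' Per-model evaluation table
#'
#' One row per candidate model (plus any selector rows the caller adds):
#' mean observed Dice, its SD, prediction MAE, Pearson r and p-value -
#' the standard per-model summary of segmentation and quality-control
#' performance.
#'
#' @param observed numeric matrix, rows = images, columns = model ids;
#'   observed Dice against ground truth.
#' @param predicted matrix of identical layout with predicted Dice.
#' @return data.frame with columns `model_id`, `mean_dsc`, `sd_dsc`,
#'   `mae`, `r`, `p_value`.
#' @export
qc_report <- function(observed, predicted) {
  observed <- as.matrix(observed)
  predicted <- as.matrix(predicted)
  stopifnot(identical(dim(observed), dim(predicted)),
            identical(colnames(observed), colnames(predicted)))
  rows <- lapply(colnames(observed), function(id) {
    pa <- prediction_accuracy(predicted[, id], observed[, id])
    data.frame(model_id = id,
               mean_dsc = mean(observed[, id]),
               sd_dsc = stats::sd(observed[, id]),
               mae = pa$mae, r = pa$r, p_value = pa$p_value)
  })
  do.call(rbind, rows)
}

#' Bland-Altman scatter plot with tier colouring
#'
#' @param ba a [bland_altman()] result.
#' @param means pairwise means (x axis), same length as `ba$rel_diff`.
#' @param tier optional factor/character for point colouring.
#' @param file optional PNG path.
#' @export
plot_bland_altman <- function(ba, means, tier = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 540)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  col <- if (is.null(tier)) "black" else {
    pal <- grDevices::hcl.colors(length(unique(tier)), "Dark 3")
    pal[as.integer(factor(tier))]
  }
  graphics::plot(means, ba$rel_diff, pch = 19, col = col,
                 xlab = "Mean of automatic and manual T1 (ms)",
                 ylab = "Relative difference (%)",
                 main = "Bland-Altman agreement of myocardial T1")
  graphics::abline(h = c(ba$bias, ba$lower, ba$upper),
                   lty = c(1, 2, 2), col = "grey30")
  if (!is.null(tier)) {
    lv <- levels(factor(tier))
    graphics::legend("topright", legend = lv, pch = 19,
                     col = grDevices::hcl.colors(length(lv), "Dark 3"))
  }
  invisible(ba)
}
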