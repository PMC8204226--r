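#' Quality-control-driven selection of the final segmentation
#'
#' Given predicted Dice scores for every candidate of an image, returns the
#' candidate with the highest prediction as the final segmentation `S*`
#' (the core QCD rule), together with its predicted Dice as the image's
#' quality-control score. The `qcd_lite` variant restricts the candidate
#' pool to the single-model masks (combined candidates excluded; its
#' predictors are fitted on the singles-only Dice matrix). Ties are broken
#' deterministically in favour of the first candidate in canonical order.
#'
#' @param cs a [build_candidates()] result.
#' @param predictions named numeric vector of predicted Dice covering the
#'   variant's whole candidate pool (all candidates for `"qcd"`, singles
#'   for `"qcd_lite"`). Missing a pooled candidate is an error.
#' @param variant `"qcd"` or `"qcd_lite"`.
#' @return Object of class `qcd_result`: `final_mask`, `selected_model_id`,
#'   `predicted_dsc`, `per_candidate_predictions`, `variant`.
#' @export
qcd_select <- function(cs, predictions, variant = c("qcd", "qcd_lite")) {
  stopifnot(inherits(cs, "candidate_set"))
  variant <- match.arg(variant)
  pool <- candidates(cs, if (variant == "qcd_lite") "singles" else "all")
  missing <- setdiff(names(pool), names(predictions))
  if (length(missing)) {
    stop("missing predictions for candidate(s): ", paste(missing, collapse = ", "))
  }
  preds <- predictions[names(pool)]  # canonical order; ties -> first
  best <- which.max(preds)
  structure(list(
    final_mask = pool[[best]],
    selected_model_id = names(pool)[best],
    predicted_dsc = unname(preds[best]),
    per_candidate_predictions = preds,
    variant = variant
  ), class = "qcd_result")
}

#' Weighted-average variant of QCD selection
#'
#' Instead of picking one candidate, every candidate mask is weighted by
#' its predicted Dice; the weight-normalized soft map is binarized at 0.5
#' (exactly 0.5 counts as foreground). The reported quality score is the
#' correspondingly weighted average of the predictions,
#' `sum(w * p) / sum(w)` with `w = p`.
#'
#' @inheritParams qcd_select
#' @return A `qcd_result` with `selected_model_id = "weighted_average"`.
#' @export
weighted_average_select <- function(cs, predictions) {
  stopifnot(inherits(cs, "candidate_set"))
  pool <- candidates(cs, "all")
  missing <- setdiff(names(pool), names(predictions))
  if (length(missing)) {
    stop("missing predictions for candidate(s): ", paste(missing, collapse = ", "))
  }
  w <- predictions[names(pool)]
  if (any(w < 0)) stop("weights (predicted Dice) must be >= 0")
  if (sum(w) <= 0) stop("all candidate weights are zero; cannot form a weighted average")
  soft <- Reduce(`+`, Map(function(m, wi) as_mask_matrix(m) * wi, pool, w)) / sum(w)
  structure(list(
    final_mask = seg_mask(soft >= 0.5),
    selected_model_id = "weighted_average",
    predicted_dsc = sum(w * w) / sum(w),
    per_candidate_predictions = w,
    variant = "weighted_average"
  ), class = "qcd_result")
}

#' @export
print.qcd_result <- function(x, ...) {
  cat(sprintf("<qcd_result> variant '%s': selected '%s' (predicted Dice %.4f)\n",
              x$variant, x$selected_model_id, x$predicted_dsc))
  invisible(x)
}

#' Tabulate how often each candidate model is selected
#'
#' @param results list of `qcd_result`s.
#' @return data.frame with `model_id` and `count`, descending.
#' @export
selection_frequency <- function(results) {
  ids <- vapply(results, `[[`, "", "selected_model_id")
  tab <- sort(table(ids), decreasing = TRUE)
  data.frame(model_id = names(tab), count = as.integer(tab),
             row.names = NULL)
}
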