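#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard overlap metric in `[0, 1]`.
#' Two empty masks agree perfectly by convention (returns 1); one empty and
#' one non-empty mask are maximally discordant (returns 0, which the
#' general formula already gives).
#'
#' @param a,b [seg_mask()]s of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  check_same_shape(list(a, b))
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(as_mask_matrix(a) & as_mask_matrix(b)) / (sa + sb)
}

pair_key <- function(m, n) paste(m, n, sep = "--")

#' Inter-candidate Dice association matrix
#'
#' Computes the Dice coefficient for every unordered pair of distinct
#' candidates (singles and combined) of one image. Because Dice is
#' symmetric, one entry per unordered pair carries all the information;
#' with `|M|` candidates there are `|M|(|M|-1)/2` entries. The pair order
#' (`feature_order`) follows the canonical candidate order and is identical
#' for every image, so matrix entries line up as regression features across
#' images.
#'
#' @param cs a [build_candidates()] result, or a named list of masks.
#' @param pool passed to [candidates()] when `cs` is a candidate set.
#' @return Object of class `dsc_matrix`: list with `values` (named numeric,
#'   names `"m--n"`), `feature_order` (character), `candidate_ids`.
#' @export
dsc_matrix <- function(cs, pool = "all") {
  masks <- if (inherits(cs, "candidate_set")) candidates(cs, pool) else cs
  if (length(masks) < 2) stop("need at least 2 candidates")
  ids <- names(masks)
  if (is.null(ids) || anyDuplicated(ids)) stop("candidates must be uniquely named")
  check_same_shape(masks)
  pairs <- utils::combn(ids, 2)
  vals <- apply(pairs, 2, function(p) dsc(masks[[p[1]]], masks[[p[2]]]))
  names(vals) <- pair_key(pairs[1, ], pairs[2, ])
  structure(list(values = vals, feature_order = names(vals),
                 candidate_ids = ids),
            class = "dsc_matrix")
}

#' @export
print.dsc_matrix <- function(x, ...) {
  cat(sprintf("<dsc_matrix> %d candidates, %d pairwise entries (mean %.3f)\n",
              length(x$candidate_ids), length(x$values), mean(x$values)))
  invisible(x)
}

#' Write a Dice matrix as a two-column CSV (pair, value)
#'
#' @param dm a [dsc_matrix()].
#' @param path output CSV path.
#' @export
write_dsc_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dsc_matrix"))
  utils::write.csv(data.frame(pair = dm$feature_order,
                              value = unname(dm$values)),
                   path, row.names = FALSE)
  invisible(path)
}

# minimum-norm least squares of y on centered X via SVD pseudoinverse;
# equals ordinary least squares when X (centered) has full column rank.
# `tol` is the relative singular-value cutoff: directions of the design with
# d_i <= tol * d_1 are dropped (truncated-SVD / principal-components
# regression), which tames noise amplification in strongly collinear designs
min_norm_ols <- function(X, y, tol = 1e-10) {
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- mean(y)
  sv <- svd(Xc)
  pos <- sv$d > tol * max(sv$d, 0)
  rank <- sum(pos)
  beta <- if (rank == 0) {
    rep(0, ncol(X))
  } else {
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y - ybar)) / sv$d[pos])
  }
  list(alpha = ybar - sum(xbar * beta), beta = as.numeric(beta), rank = rank)
}

#' Fit per-model Dice-quality predictors
#'
#' For each candidate model `m`, fits a multiple linear regression of the
#' observed `DSC(S_m, S_GT)` (ground truth available in the training data)
#' on all entries of the inter-candidate Dice matrix. The feature vector is
#' the full matrix - every unordered pair, including pairs not involving
#' `m` - so each predictor sees the ensemble's complete disagreement
#' pattern. Fitting is ordinary least squares, solved by a minimum-norm SVD
#' factorization; a rank-deficient design is handled by the same route with
#' a warning (the minimum-norm solution is returned).
#'
#' @param matrices list of [dsc_matrix()]s, one per training image, all
#'   sharing one `feature_order`.
#' @param observed numeric matrix or data.frame, rows = training images in
#'   the order of `matrices`, columns = candidate model ids; entries are
#'   observed Dice against ground truth, in `[0, 1]`.
#' @param sv_tol relative singular-value tolerance of the design: directions
#'   with singular value at or below `sv_tol` times the largest are dropped
#'   from the solution. The default (`1e-10`) keeps the fit an exact
#'   ordinary-least-squares solve and only guards against true rank
#'   deficiency. A larger value (the end-to-end study uses `1e-2`) performs
#'   truncated-SVD regression, which stabilizes predictions when the Dice
#'   features are strongly collinear and the training set is small relative
#'   to the 66 features - untamed, the near-null directions can amplify
#'   noise into wild out-of-distribution extrapolations.
#' @return Named list of `quality_predictor` objects (fields `model_id`,
#'   `alpha`, `betas`, `feature_order`).
#' @export
fit_quality_predictors <- function(matrices, observed, sv_tol = 1e-10) {
  if (length(matrices) == 0) stop("no training matrices supplied")
  fo <- matrices[[1]]$feature_order
  same <- vapply(matrices, function(m) identical(m$feature_order, fo), TRUE)
  if (!all(same)) stop("all training matrices must share one feature_order")
  observed <- as.matrix(observed)
  if (nrow(observed) != length(matrices)) {
    stop("`observed` must have one row per training matrix")
  }
  if (anyNA(observed) || any(observed < 0 | observed > 1)) {
    stop("observed Dice targets must lie in [0, 1]")
  }
  X <- do.call(rbind, lapply(matrices, function(m) unname(m$values)))
  if (nrow(X) < length(fo) + 1) {
    warning(sprintf(
      "only %d training images for %d features; fit is underdetermined (minimum-norm solution)",
      nrow(X), length(fo)))
  }
  preds <- lapply(colnames(observed), function(id) {
    fit <- min_norm_ols(X, observed[, id], tol = sv_tol)
    if (fit$rank < ncol(X) && nrow(X) >= ncol(X) + 1 && sv_tol <= 1e-8) {
      warning(sprintf("rank-deficient design for model '%s' (rank %d of %d); minimum-norm least squares used",
                      id, fit$rank, ncol(X)))
    }
    structure(list(model_id = id, alpha = fit$alpha,
                   betas = stats::setNames(fit$beta, fo),
                   feature_order = fo),
              class = "quality_predictor")
  })
  stats::setNames(preds, colnames(observed))
}

#' Predict a candidate's Dice against (absent) ground truth
#'
#' Evaluates the fitted linear model `alpha_m + sum_x beta_mx * x` over the
#' image's Dice-matrix entries and clips the result to `[0, 1]`. The
#' matrix's feature order must match the order the predictor was trained
#' with; a mismatch is an error, never silently reordered.
#'
#' @param qp a `quality_predictor` from [fit_quality_predictors()].
#' @param dm a [dsc_matrix()] for the image to score.
#' @return Predicted Dice, scalar in `[0, 1]`.
#' @export
predict_dsc <- function(qp, dm) {
  stopifnot(inherits(qp, "quality_predictor"), inherits(dm, "dsc_matrix"))
  if (!identical(qp$feature_order, dm$feature_order)) {
    stop("feature order of the Dice matrix does not match the predictor's training order")
  }
  raw <- qp$alpha + sum(qp$betas * dm$values)
  min(max(raw, 0), 1)
}

#' Predict Dice for every candidate of an image
#'
#' @param predictors named list from [fit_quality_predictors()].
#' @param dm the image's [dsc_matrix()].
#' @return Named numeric vector of predicted Dice, one per predictor.
#' @export
predict_all_dsc <- function(predictors, dm) {
  vapply(predictors, predict_dsc, numeric(1), dm = dm)
}

#' Serialize quality predictors to JSON
#'
#' Mirrors a per-model coefficient listing: each entry holds `model_id`,
#' `alpha`, the `feature_order`, and `betas`.
#'
#' @param predictors named list of `quality_predictor`s.
#' @param path output JSON path.
#' @export
write_predictors <- function(predictors, path) {
  out <- lapply(predictors, function(p) {
    list(model_id = p$model_id, alpha = p$alpha,
         feature_order = p$feature_order, betas = unname(p$betas))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read quality predictors from JSON
#'
#' @param path JSON path written by [write_predictors()].
#' @return Named list of `quality_predictor` objects.
#' @export
read_predictors <- function(path) {
  raw <- jsonlite::read_json(path)
  preds <- lapply(raw, function(p) {
    fo <- unlist(p$feature_order)
    structure(list(model_id = p$model_id, alpha = p$alpha,
                   betas = stats::setNames(unlist(p$betas), fo),
                   feature_order = fo),
              class = "quality_predictor")
  })
  stats::setNames(preds, vapply(preds, `[[`, "", "model_id"))
}
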