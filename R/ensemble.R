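#' Combine single-model segmentations by label voting
#'
#' The single-model masks are summed pixel-wise and thresholded at `t`
#' votes: a pixel is foreground in the combined mask `K_t` iff at least `t`
#' of the single models label it foreground. `t = 1` gives the union,
#' `t = |J|` the intersection, and the combined masks are nested:
#' `K_1 >= K_2 >= ... >= K_|J|`.
#'
#' @param singles list of [seg_mask()]s sharing one shape (the set `J`).
#' @param t vote threshold, integer in `1..length(singles)`.
#' @return A [seg_mask()].
#' @export
vote_combine <- function(singles, t) {
  if (length(singles) == 0) stop("`singles` must be a non-empty list of masks")
  if (t < 1 || t > length(singles)) {
    stop(sprintf("vote threshold t = %s out of range 1..%d", t, length(singles)))
  }
  check_same_shape(singles)
  counts <- Reduce(`+`, lapply(singles, as_mask_matrix))
  seg_mask(counts >= t)
}

#' Pixel-wise agreement map of an ensemble
#'
#' Counts, for every pixel, how many single models label it myocardium.
#' Thresholding the counts at `t` reproduces exactly the combined mask
#' `K_t` of [vote_combine()]; plotted, the map visualizes where the
#' ensemble agrees and where it is uncertain.
#'
#' @param singles list of [seg_mask()]s sharing one shape.
#' @return An object of class `agreement_map`: list with `counts` (integer
#'   matrix in `0..max_level`) and `max_level` (`length(singles)`).
#' @export
agreement_map <- function(singles) {
  if (length(singles) == 0) stop("`singles` must be a non-empty list of masks")
  check_same_shape(singles)
  counts <- Reduce(`+`, lapply(singles, as_mask_matrix))
  structure(list(counts = counts, max_level = length(singles)),
            class = "agreement_map")
}

#' @export
print.agreement_map <- function(x, ...) {
  cat(sprintf("<agreement_map> %d x %d pixels, %d models, %d contested pixels\n",
              nrow(x$counts), ncol(x$counts), x$max_level,
              sum(x$counts > 0 & x$counts < x$max_level)))
  invisible(x)
}

#' Render an agreement map with a discrete colour scale
#'
#' Colours each pixel by the number of agreeing models (1 = lowest
#' agreement up to `max_level` = unanimous); background (0 votes) is black.
#'
#' @param am an [agreement_map()].
#' @param file optional PNG path; if given the plot is written there.
#' @param main plot title.
#' @export
plot_agreement <- function(am, file = NULL, main = "Segmentation agreement") {
  stopifnot(inherits(am, "agreement_map"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- c("black", grDevices::hcl.colors(am$max_level, "Viridis"))
  old <- graphics::par(mar = c(2, 2, 3, 6))
  on.exit(graphics::par(old), add = TRUE)
  # transpose + reverse so row 1 is drawn at the top
  z <- t(am$counts)[, nrow(am$counts):1]
  graphics::image(z, col = pal, breaks = seq(-0.5, am$max_level + 0.5, 1),
                  axes = FALSE, main = main, useRaster = TRUE)
  graphics::legend(x = 1.02, y = 1, xpd = NA, bty = "n",
                   legend = am$max_level:1,
                   fill = rev(grDevices::hcl.colors(am$max_level, "Viridis")),
                   title = "votes")
  invisible(am)
}

#' Build the full candidate set: single and combined segmentations
#'
#' From `|J|` single-model masks, label voting produces `|J|` combined
#' candidates (`combined1` ... `combined|J|`, thresholds 1..|J|), so six
#' networks yield twelve candidates in total. Combined masks are always
#' derived from the single-model masks only. Candidate order is canonical -
#' singles in the order supplied (networks by ascending depth), then
#' combined masks by ascending threshold - and every downstream feature
#' ordering relies on it.
#'
#' @param singles named list of [seg_mask()]s; names are model ids (e.g.
#'   `"unet7"`), in canonical (ascending-depth) order.
#' @param map_id identifier of the source image.
#' @return An object of class `candidate_set`: list with `singles`,
#'   `combined` (both named lists of masks) and `map_id`.
#' @export
build_candidates <- function(singles, map_id = "map") {
  if (length(singles) < 2) stop("need at least 2 single-model masks")
  if (is.null(names(singles)) || anyNA(names(singles)) ||
      any(names(singles) == "") || anyDuplicated(names(singles))) {
    stop("`singles` must be a uniquely named list of masks")
  }
  check_same_shape(singles)
  counts <- Reduce(`+`, lapply(singles, as_mask_matrix))
  combined <- lapply(seq_along(singles), function(t) seg_mask(counts >= t))
  names(combined) <- paste0("combined", seq_along(singles))
  structure(list(singles = singles, combined = combined, map_id = map_id),
            class = "candidate_set")
}

#' All candidates of a candidate set, in canonical order
#'
#' @param cs a [build_candidates()] result.
#' @param pool `"all"` (singles then combined) or `"singles"`.
#' @return Named list of [seg_mask()]s.
#' @export
candidates <- function(cs, pool = c("all", "singles")) {
  stopifnot(inherits(cs, "candidate_set"))
  pool <- match.arg(pool)
  if (pool == "singles") cs$singles else c(cs$singles, cs$combined)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> '%s': %d singles + %d combined\n",
              x$map_id, length(x$singles), length(x$combined)))
  invisible(x)
}
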