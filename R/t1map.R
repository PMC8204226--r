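#' T1 map container
#'
#' A `t1_map` is a 2D numeric matrix of longitudinal relaxation times in
#' milliseconds, one value per pixel, with optional pixel spacing metadata.
#' Maps are processed per-slice: short-axis T1 mapping produces a single 2D
#' map per acquisition, so no volume support is provided.
#'
#' @param values numeric matrix of T1 values (ms).
#' @param pixel_spacing numeric length-2, in-plane pixel spacing in mm
#'   (row, col). Purely descriptive; all geometry in this package is in
#'   pixel units.
#' @return An object of class `t1_map` (a matrix with attributes).
#' @export
t1_map <- function(values, pixel_spacing = c(1, 1)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a 2D numeric matrix (one short-axis slice)")
  }
  storage.mode(values) <- "double"
  structure(values,
            pixel_spacing = as.numeric(pixel_spacing),
            class = c("t1_map", "matrix", "array"))
}

#' Binary myocardium segmentation mask
#'
#' A `seg_mask` is a binary (0/1 integer) matrix aligned pixel-for-pixel with
#' a [t1_map()]: 1 marks left-ventricular myocardium, 0 everything else.
#'
#' @param values matrix (logical or numeric with values in \{0, 1\}).
#' @return An object of class `seg_mask` (an integer matrix).
#' @export
seg_mask <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.logical(values)) values <- values * 1L
  if (!all(values %in% c(0L, 1L))) {
    stop("mask values must be binary (0/1)")
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("seg_mask", "matrix", "array"))
}

#' @export
print.t1_map <- function(x, ...) {
  cat(sprintf("<t1_map> %d x %d pixels, T1 range [%.0f, %.0f] ms\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %d x %d pixels, %d foreground (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# shared shape check used across modules
check_same_shape <- function(masks) {
  dims <- vapply(masks, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all masks must share a single shape")
  }
  invisible(TRUE)
}

as_mask_matrix <- function(m) {
  # strip class so arithmetic over lists of masks stays plain integer
  unclass(m)
}
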