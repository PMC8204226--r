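#' Read and write T1 maps and masks as NIfTI
#'
#' The interchange format is NIfTI (`.nii` / `.nii.gz`): maps are stored as
#' float32, masks as uint8. The framework is strictly 2D per-slice; 3D
#' volumes are rejected with guidance (a trailing singleton dimension is
#' tolerated and dropped). Masks holding \{0, 255\} are coerced to \{0, 1\}
#' with a warning; any other non-binary content is an error.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return [read_t1_map()] returns a [t1_map()]; [read_seg_mask()] a
#'   [seg_mask()]. The writers return `path` invisibly.
#' @name qcdseg-io
NULL

check_2d <- function(arr, path) {
  d <- dim(arr)
  d <- d[d > 1]
  if (length(d) > 2) {
    stop(sprintf(
      "'%s' is a %dD volume; this framework processes single 2D short-axis slices - split the volume and pass one slice at a time",
      path, length(dim(arr))))
  }
  matrix(as.vector(arr)[seq_len(prod(d))], d[1], d[2])
}

#' @rdname qcdseg-io
#' @param map a [t1_map()].
#' @export
write_t1_map <- function(map, path) {
  stopifnot(inherits(map, "t1_map"))
  RNifti::writeNifti(RNifti::asNifti(unclass(map)), path, datatype = "float")
  invisible(path)
}

#' @rdname qcdseg-io
#' @export
read_t1_map <- function(path) {
  arr <- RNifti::readNifti(path)
  t1_map(check_2d(arr, path), pixel_spacing = RNifti::pixdim(arr)[1:2])
}

#' @rdname qcdseg-io
#' @param mask a [seg_mask()].
#' @export
write_seg_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  RNifti::writeNifti(RNifti::asNifti(unclass(mask)), path, datatype = "uint8")
  invisible(path)
}

#' @rdname qcdseg-io
#' @export
read_seg_mask <- function(path) {
  arr <- check_2d(RNifti::readNifti(path), path)
  vals <- sort(unique(as.vector(arr)))
  if (all(vals %in% c(0, 255)) && 255 %in% vals) {
    warning("mask uses {0, 255} labels; coercing to {0, 1}")
    arr <- arr / 255
  }
  if (!all(arr %in% c(0, 1))) {
    stop(sprintf("'%s' is not a binary mask (values outside {0,1}/{0,255})", path))
  }
  seg_mask(arr == 1)
}
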