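#' Configuration of one U-net in the zoo
#'
#' The zoo contains six encoder-decoder fully-convolutional networks of
#' graded depth, referred to by their total count of convolutional plus
#' transposed-convolutional layers: the supported (layer_count,
#' skip_connections) pairs are exactly (7,1), (11,2), (15,3), (19,4),
#' (23,5), (27,6). For `S` skip connections the realization is: `S` encoder
#' stages of two 3x3 convolutions followed by 2x2 max pooling, a
#' two-convolution bottleneck, `S` decoder stages of a 2x2 transposed
#' convolution (stride 2) plus one 3x3 convolution after concatenation
#' with the matching encoder feature map, and a final 1x1 convolution to
#' two class scores per pixel - `4S + 3` countable layers in total.
#' Channel widths start at `base_channels` and double per pooling stage up
#' to `channel_cap`.
#'
#' @param layer_count odd integer in \{7, 11, 15, 19, 23, 27\}.
#' @param skip_connections integer in 1..6; must pair with `layer_count`.
#' @param base_channels channels of the first encoder stage.
#' @param channel_cap maximum channels at any depth.
#' @param input_size square image size in pixels; must be divisible by
#'   `2^skip_connections`.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(layer_count, skip_connections = (layer_count - 3) / 4,
                        base_channels = 8L, channel_cap = 64L,
                        input_size = 64L) {
  supported <- cbind(layer_count = seq(7, 27, by = 4), skip_connections = 1:6)
  ok <- any(supported[, 1] == layer_count & supported[, 2] == skip_connections)
  if (!ok) {
    stop(sprintf(
      "unsupported architecture (%s layers, %s skips); supported pairs: %s",
      format(layer_count), format(skip_connections),
      paste(sprintf("(%d,%d)", supported[, 1], supported[, 2]), collapse = " ")))
  }
  if (input_size %% 2^skip_connections != 0) {
    stop(sprintf("input_size %d must be divisible by 2^%d = %d for %d pooling stages",
                 input_size, skip_connections, 2^skip_connections,
                 skip_connections))
  }
  structure(list(layer_count = as.integer(layer_count),
                 skip_connections = as.integer(skip_connections),
                 base_channels = as.integer(base_channels),
                 channel_cap = as.integer(channel_cap),
                 input_size = as.integer(input_size)),
            class = "unet_config")
}

#' Build an untrained U-net from its configuration
#'
#' Weight initialization is He-scaled Gaussian, fully determined by `seed`.
#'
#' @param config a [unet_config()].
#' @param model_id name of the model; default `"unet<layer_count>"`.
#' @param seed integer seed for weight initialization.
#' @return An object of class `seg_model` holding the layer graph and
#'   weights.
#' @export
build_unet <- function(config, model_id = paste0("unet", config$layer_count),
                       seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  S <- config$skip_connections
  sz <- config$input_size
  enc_ch <- pmin(config$base_channels * 2^(0:(S - 1)), config$channel_cap)
  bott_ch <- min(config$base_channels * 2^S, config$channel_cap)

  rng <- local_rng(seed)
  layers <- list()
  c_in <- 1L
  res <- sz
  for (i in seq_len(S)) {
    layers <- c(layers, list(nn_conv3(res, res, c_in, enc_ch[i])))
    l2 <- nn_conv3(res, res, enc_ch[i], enc_ch[i])
    l2$skip_tag <- paste0("skip", i)      # output stored for the decoder
    layers <- c(layers, list(l2))
    layers <- c(layers, list(nn_pool(res, res, enc_ch[i])))
    c_in <- enc_ch[i]
    res <- res %/% 2L
  }
  layers <- c(layers, list(nn_conv3(res, res, c_in, bott_ch)))
  layers <- c(layers, list(nn_conv3(res, res, bott_ch, bott_ch)))
  c_in <- bott_ch
  for (i in rev(seq_len(S))) {
    layers <- c(layers, list(nn_tconv(res, res, c_in, enc_ch[i])))
    res <- res * 2L
    layers <- c(layers, list(nn_concat(paste0("skip", i), enc_ch[i], enc_ch[i])))
    layers <- c(layers, list(nn_conv3(res, res, 2L * enc_ch[i], enc_ch[i])))
    c_in <- enc_ch[i]
  }
  layers <- c(layers, list(nn_conv1(res, res, c_in, 2L)))
  restore_rng(rng)

  structure(list(config = config, model_id = model_id, layers = layers,
                 trained = FALSE),
            class = "seg_model")
}

#' Audit a built network's depth and skip connections
#'
#' Counts the actual convolutional + transposed-convolutional layers and
#' skip links in the layer graph (not the configuration), so the audit can
#' verify the built architecture against its contract.
#'
#' @param model a [build_unet()] result.
#' @return List with `layer_count`, `skip_connections`, and a breakdown by
#'   layer type.
#' @export
unet_audit <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  types <- vapply(model$layers, `[[`, "", "type")
  list(layer_count = sum(types %in% c("conv3", "conv1", "tconv")),
       skip_connections = sum(types == "concat"),
       by_type = table(types))
}

#' @export
print.seg_model <- function(x, ...) {
  a <- unet_audit(x)
  cat(sprintf("<seg_model> '%s': %d conv/tconv layers, %d skips, input %dx%d, %s\n",
              x$model_id, a$layer_count, a$skip_connections,
              x$config$input_size, x$config$input_size,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Binarize two-class pixel logits into a mask
#'
#' A pixel is foreground iff its softmax foreground probability is at
#' least `threshold`. At `threshold = 0.5` this coincides with the
#' two-class argmax, with ties going to foreground.
#'
#' @param logits numeric matrix `[n_pixels, 2]` (background, foreground
#'   scores) or array `H x W x 2`.
#' @param threshold foreground-probability threshold in (0, 1).
#' @param shape optional `c(H, W)` to reshape a `[n_pixels, 2]` input.
#' @return A [seg_mask()] when the spatial shape is known, otherwise a
#'   binary vector.
#' @export
mask_from_logits <- function(logits, threshold = 0.5, shape = NULL) {
  if (length(dim(logits)) == 3) {
    shape <- dim(logits)[1:2]
    logits <- cbind(as.vector(logits[, , 1]), as.vector(logits[, , 2]))
  }
  fg <- softmax_fg(logits) >= threshold
  if (is.null(shape)) return(as.integer(fg))
  seg_mask(matrix(fg, shape[1], shape[2]))
}

#' Segment a T1 map with one trained network
#'
#' The map is standardized per image (zero mean, unit variance), passed
#' through the network, and the foreground-probability map is binarized at
#' `tc$binarize_threshold`.
#'
#' @param model a trained [build_unet()] model.
#' @param map a [t1_map()] whose shape equals the model's `input_size`.
#' @param tc a [train_config()]; only `binarize_threshold` is used.
#' @return A [seg_mask()] of the same shape as `map`.
#' @export
predict_mask <- function(model, map, tc = train_config()) {
  stopifnot(inherits(model, "seg_model"))
  sz <- model$config$input_size
  if (!all(dim(map) == c(sz, sz))) {
    stop(sprintf("map shape %dx%d does not match model input %dx%d",
                 nrow(map), ncol(map), sz, sz))
  }
  x <- normalize_map(map)
  logits <- net_forward(model, x, training = FALSE)$logits
  mask_from_logits(logits, tc$binarize_threshold, shape = c(sz, sz))
}

#' Save / load a segmentation model
#'
#' The weight state is serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the architecture manifest (model id, layer and
#' skip counts, channels, input size) for inspection without loading.
#'
#' @param model a `seg_model`.
#' @param path output `.rds` path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  a <- unet_audit(model)
  jsonlite::write_json(
    list(model_id = model$model_id,
         layer_count = a$layer_count,
         skip_connections = a$skip_connections,
         base_channels = model$config$base_channels,
         channel_cap = model$config$channel_cap,
         input_size = model$config$input_size,
         trained = model$trained),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
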