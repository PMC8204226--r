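#' Training configuration for the U-net zoo
#'
#' Adam on two-class pixel-wise softmax cross-entropy. Defaults follow the
#' zoo's training protocol (60 epochs, Adam at learning rate 1e-3); tests
#' and desk-scale experiments pass fewer epochs.
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size gradients are averaged over minibatches of this size.
#' @param seed integer seed controlling shuffling.
#' @param binarize_threshold foreground-probability threshold in (0, 1)
#'   used when binarizing predictions.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 60L, learning_rate = 1e-3, batch_size = 8L,
                         seed = 1L, binarize_threshold = 0.5) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop("binarize_threshold must lie in (0, 1)")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 binarize_threshold = binarize_threshold),
            class = "train_config")
}

sample_xy <- function(sample) {
  list(x = normalize_map(sample$t1_map),
       y = as.integer(as.vector(as_mask_matrix(sample$gt_mask))))
}

#' Train one network of the zoo
#'
#' Minibatch Adam on pixel-wise softmax cross-entropy. The history records
#' the mean training loss per epoch and, when a validation set is given,
#' the mean validation Dice per epoch. Runs are reproducible from
#' `tc$seed`. A non-finite loss aborts with a diagnostic naming the epoch
#' and step.
#'
#' @param model a [build_unet()] model.
#' @param train non-empty list of samples, each with `t1_map` and `gt_mask`
#'   (e.g. `phantom_sample`s).
#' @param val optional validation list of the same form.
#' @param tc a [train_config()].
#' @return The trained `seg_model`, with the per-epoch history in
#'   `model$history` (data.frame: epoch, train_loss, val_dsc).
#' @export
train_model <- function(model, train, val = NULL, tc = train_config()) {
  stopifnot(inherits(model, "seg_model"), inherits(tc, "train_config"))
  if (length(train) == 0) stop("training set is empty")
  sz <- model$config$input_size
  for (s in train) {
    if (!all(dim(s$t1_map) == c(sz, sz)) || !all(dim(s$gt_mask) == c(sz, sz))) {
      stop("training maps/masks must match the model input size and be aligned")
    }
  }
  data <- lapply(train, sample_xy)
  state <- adam_init(model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dsc = numeric())

  rng <- local_rng(tc$seed)
  on.exit(restore_rng(rng), add = TRUE)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(length(data))
    losses <- numeric(0)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    for (bi in seq_along(batches)) {
      acc <- NULL
      batch <- batches[[bi]]
      bloss <- 0
      for (i in batch) {
        fw <- net_forward(model, data[[i]]$x, training = TRUE)
        ce <- softmax_ce(fw$logits, data[[i]]$y)
        if (!is.finite(ce$loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d (model '%s'): training diverged - lower the learning rate",
                       epoch, bi, model$model_id))
        }
        bloss <- bloss + ce$loss
        acc <- add_grads(acc, net_backward(model, fw$caches, ce$dlogits))
      }
      acc <- scale_grads(acc, 1 / length(batch))
      st <- adam_step(model, acc, state, tc$learning_rate)
      model <- st$model
      state <- st$state
      losses <- c(losses, bloss / length(batch))
    }
    val_dsc <- NA_real_
    if (length(val) > 0) {
      val_dsc <- mean(vapply(val, function(s) {
        dsc(predict_mask(model, s$t1_map, tc), s$gt_mask)
      }, numeric(1)))
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dsc = val_dsc))
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Build and train the full zoo of networks
#'
#' One network per entry of `depths`, each built and trained independently
#' (weights initialized from `seed` offset by the network's position).
#'
#' @param train,val sample lists as in [train_model()].
#' @param depths layer counts, default the full zoo `c(7, 11, ..., 27)`.
#' @param tc a [train_config()].
#' @param input_size image size the networks operate on.
#' @param base_channels,channel_cap channel widths, see [unet_config()].
#' @param seed integer; network `i` initializes from `seed + i`.
#' @param verbose print one line per trained network.
#' @return Named list of trained `seg_model`s, names `"unet<depth>"`,
#'   ascending depth.
#' @export
train_zoo <- function(train, val = NULL, depths = seq(7, 27, by = 4),
                      tc = train_config(), input_size = 64L,
                      base_channels = 8L, channel_cap = 64L,
                      seed = 1L, verbose = FALSE) {
  depths <- sort(depths)
  zoo <- list()
  for (i in seq_along(depths)) {
    cfg <- unet_config(depths[i], base_channels = base_channels,
                       channel_cap = channel_cap, input_size = input_size)
    model <- build_unet(cfg, seed = seed + i)
    t0 <- Sys.time()
    model <- train_model(model, train, val, tc)
    if (verbose) {
      message(sprintf("trained %s: final loss %.4f, val Dice %s (%.1f s)",
                      model$model_id, utils::tail(model$history$train_loss, 1),
                      formatC(utils::tail(model$history$val_dsc, 1), digits = 3),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    zoo[[model$model_id]] <- model
  }
  zoo
}

#' Candidate segmentations of one map from a trained zoo
#'
#' Runs every network, then label voting, returning the full candidate
#' set (singles in ascending depth, then combined masks).
#'
#' @param zoo named list of trained models ([train_zoo()]).
#' @param map a [t1_map()].
#' @param tc a [train_config()] (binarization threshold).
#' @param map_id identifier for the candidate set.
#' @return A [build_candidates()] result.
#' @export
segment_with_zoo <- function(zoo, map, tc = train_config(), map_id = "map") {
  singles <- lapply(zoo, predict_mask, map = map, tc = tc)
  build_candidates(singles, map_id = map_id)
}
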