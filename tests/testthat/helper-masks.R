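# small fixture builders shared across test files

random_mask <- function(h = 8, w = 8, p = 0.4) {
  seg_mask(matrix(runif(h * w) < p, h, w))
}

random_mask_set <- function(n, h = 8, w = 8, p = 0.4) {
  lapply(seq_len(n), function(i) random_mask(h, w, p))
}

named_mask_set <- function(n, h = 8, w = 8, p = 0.4) {
  stats::setNames(random_mask_set(n, h, w, p), paste0("model", seq_len(n)))
}

# brute-force voting oracle: per-pixel loop, independent of vote_combine
brute_force_vote <- function(masks, t) {
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    votes <- 0L
    for (m in masks) votes <- votes + m[r, c]
    out[r, c] <- as.integer(votes >= t)
  }
  out
}

# one tiny quick phantom sample; annulus scaled to the image
tiny_sample <- function(seed = 1, image_size = 32, tier = "excellent") {
  generate_phantom(phantom_spec(image_size = image_size,
                                endo_radius = image_size / 5,
                                wall_thickness = image_size / 10,
                                tier = tier, seed = seed))
}
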