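#' Image-quality tiers for synthetic T1 maps
#'
#' The phantom generator grades images into four quality tiers mirroring how
#' clinical T1 maps are scored by expert readers: from well-defined
#' myocardial borders with good contrast down to ambiguous borders with poor
#' contrast plus visible artefacts. Each tier sets the additive noise level
#' and a contrast factor that pulls the blood-pool and background means
#' toward the myocardial mean (lower contrast = harder borders). The `poor`
#' tier always carries at least one artefact.
#'
#' @format A data.frame with one row per tier: `tier`, `noise_sd` (ms),
#'   `contrast` (multiplier in (0, 1] on tissue-mean separation), and
#'   `prevalence` (default mixing proportion).
#' @export
phantom_tiers <- data.frame(
  tier       = c("excellent", "good", "acceptable", "poor"),
  noise_sd   = c(60, 110, 190, 300),
  contrast   = c(1.00, 0.85, 0.65, 0.45),
  prevalence = c(0.052, 0.235, 0.653, 0.060),
  stringsAsFactors = FALSE
)

phantom_artefact_names <- c("wraparound_clutter", "bright_blob", "contrast_fade")

#' Specification of a synthetic short-axis T1 phantom
#'
#' Defines one synthetic left-ventricular short-axis T1 map: an annular
#' myocardium of mean `t1_myocardium` around a blood pool of mean `t1_blood`,
#' on a background of mean `t1_background`, degraded according to a quality
#' `tier` (noise + contrast loss) and optional artefacts.
#'
#' Geometry is in pixel units with 0-based (row, col) coordinates; the
#' annulus is rasterized pixel-center-inside. Default tissue means emulate
#' plausible native (pre-contrast) myocardial/blood/background T1 contrast;
#' they are configuration, not physiological claims.
#'
#' @param image_size pixels per side (square image).
#' @param center numeric length-2, (row, col) sub-pixel coordinates of the
#'   blood-pool center (0-based). Default: image center.
#' @param endo_radius endocardial radius in pixels (> 0).
#' @param wall_thickness myocardial wall thickness in pixels (> 0);
#'   `endo_radius + wall_thickness` must stay inside the half-image.
#' @param t1_myocardium,t1_blood,t1_background tissue mean T1 values (ms).
#' @param tier quality tier, one of `phantom_tiers$tier`.
#' @param noise_sd additive Gaussian noise SD (ms). Default: the tier's value.
#' @param artefacts character vector, subset of
#'   `c("wraparound_clutter", "bright_blob", "contrast_fade")`. Default: none,
#'   except tier `"poor"` which draws at least one at generation time.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 96L,
                         center = NULL,
                         endo_radius = image_size / 6,
                         wall_thickness = image_size / 18,
                         t1_myocardium = 950,
                         t1_blood = 1600,
                         t1_background = 300,
                         tier = "acceptable",
                         noise_sd = NULL,
                         artefacts = NULL,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.null(center)) center <- c((image_size - 1) / 2, (image_size - 1) / 2)
  tier <- match.arg(tier, phantom_tiers$tier)
  if (is.null(noise_sd)) {
    noise_sd <- phantom_tiers$noise_sd[phantom_tiers$tier == tier]
  }
  if (!is.null(artefacts)) {
    bad <- setdiff(artefacts, phantom_artefact_names)
    if (length(bad)) stop("unknown artefacts: ", paste(bad, collapse = ", "))
  }
  spec <- structure(list(
    image_size = image_size, center = as.numeric(center),
    endo_radius = as.numeric(endo_radius),
    wall_thickness = as.numeric(wall_thickness),
    t1_myocardium = t1_myocardium, t1_blood = t1_blood,
    t1_background = t1_background, tier = tier,
    noise_sd = as.numeric(noise_sd), artefacts = artefacts,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$endo_radius <= 0) stop("endo_radius must be > 0")
  if (spec$wall_thickness <= 0) stop("wall_thickness must be > 0")
  if (spec$endo_radius + spec$wall_thickness >= spec$image_size / 2) {
    stop(sprintf(
      "annulus does not fit: endo_radius + wall_thickness = %.1f must be < image_size/2 = %.1f",
      spec$endo_radius + spec$wall_thickness, spec$image_size / 2))
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(spec)
}

# squared distance of every pixel center from `center`, 0-based coordinates
pixel_dist <- function(image_size, center) {
  r <- 0:(image_size - 1)
  dr <- (r - center[1])^2
  dc <- (r - center[2])^2
  sqrt(outer(dr, dc, `+`))
}

annulus_mask <- function(spec) {
  d <- pixel_dist(spec$image_size, spec$center)
  seg_mask(d >= spec$endo_radius &
           d < spec$endo_radius + spec$wall_thickness)
}

#' Generate one synthetic T1 phantom with its ground-truth mask
#'
#' Builds the noiseless tissue-mean image (background, blood-pool disk,
#' myocardial annulus), applies the tier's contrast factor (blood and
#' background means are pulled toward the myocardial mean; the myocardium
#' itself is unchanged, so at zero noise every myocardial pixel equals
#' `t1_myocardium` exactly), injects the requested artefacts, and adds
#' Gaussian noise. The ground-truth mask is the analytic annulus; artefacts
#' and noise never alter it.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `t1_map`
#'   ([t1_map()]), `gt_mask` ([seg_mask()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$image_size
  d <- pixel_dist(n, spec$center)
  gt <- annulus_mask(spec)

  ct <- phantom_tiers$contrast[phantom_tiers$tier == spec$tier]
  myo <- spec$t1_myocardium
  blood_eff <- myo + (spec$t1_blood - myo) * ct
  bg_eff <- myo + (spec$t1_background - myo) * ct

  img <- matrix(bg_eff, n, n)
  img[d < spec$endo_radius] <- blood_eff
  img[unclass(gt) == 1L] <- myo

  rng <- local_rng(spec$seed)
  artefacts <- spec$artefacts
  if (is.null(artefacts) && spec$tier == "poor") {
    artefacts <- sample(phantom_artefact_names,
                        size = sample(1:2, 1), replace = FALSE)
  }
  for (a in artefacts %||% character()) {
    img <- apply_artefact(img, a, spec, d)
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  }
  restore_rng(rng)

  structure(list(t1_map = t1_map(img), gt_mask = gt, spec = spec),
            class = "phantom_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed the RNG locally, restoring global state on exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

apply_artefact <- function(img, name, spec, d) {
  n <- spec$image_size
  switch(name,
    # ghost of the annulus folded onto the image edge, mimicking phase
    # wraparound: myocardium-intensity ring clutter at the left border
    wraparound_clutter = {
      ghost_center <- c(spec$center[1] + stats::runif(1, -n / 8, n / 8), 0)
      gd <- pixel_dist(n, ghost_center)
      ring <- gd >= spec$endo_radius * 0.7 &
              gd < spec$endo_radius * 0.7 + spec$wall_thickness * 1.5
      img[ring] <- spec$t1_myocardium
      img
    },
    # bright implant-like blob, placed near (possibly overlapping) the annulus
    bright_blob = {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- spec$endo_radius + spec$wall_thickness * stats::runif(1, 0.5, 2.5)
      bc <- spec$center + rad * c(sin(ang), cos(ang))
      bd <- pixel_dist(n, bc)
      sigma <- spec$wall_thickness * 1.2
      img + 1500 * exp(-(bd^2) / (2 * sigma^2))
    },
    # one-sided contrast loss: tissue separation fades across columns
    contrast_fade = {
      ramp <- seq(1, 0.3, length.out = n)
      sweep_dir <- sample(c(1, -1), 1)
      if (sweep_dir < 0) ramp <- rev(ramp)
      dev <- sweep(img - spec$t1_myocardium, 2, ramp, `*`)
      spec$t1_myocardium + dev
    },
    stop("unknown artefact: ", name))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# largest-remainder apportionment of n into proportions p (sums to n exactly)
apportion <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a seeded phantom dataset with train/validation/test splits
#'
#' Draws `n` phantoms with randomized geometry (annulus radius and wall vary
#' to emulate basal-to-apical slice variation, center jitters off-grid) and
#' quality tiers apportioned to `tier_mix` by largest remainder. The dataset
#' is split 80% / 9% / 11% into training, validation, and test partitions
#' (train and validation sizes rounded half away from zero, test takes the
#' remainder), with randomized membership. Fully reproducible from `seed`.
#'
#' @param n number of phantoms (>= 10 so every split is non-empty).
#' @param tier_mix named or ordered numeric length-4, proportions for
#'   (excellent, good, acceptable, poor); must sum to 1. Default: the
#'   prevalence column of [phantom_tiers].
#' @param seed integer seed.
#' @param image_size pixels per side for every phantom.
#' @param ... further arguments passed to [phantom_spec()] (tissue means).
#' @return A list of class `phantom_dataset` with elements `train`,
#'   `validation`, `test` (lists of `phantom_sample`), and a `manifest`
#'   data.frame (id, split, tier, geometry, seed).
#' @export
generate_dataset <- function(n, tier_mix = phantom_tiers$prevalence,
                             seed = 1L, image_size = 96L, ...) {
  if (n < 10) stop("n must be >= 10 so that every split has at least one sample")
  tier_mix <- as.numeric(tier_mix)
  if (length(tier_mix) != 4) stop("tier_mix must have 4 entries")
  if (abs(sum(tier_mix) - 1) > 1e-9) stop("tier_mix must sum to 1")

  n_train <- round_half_up(0.80 * n)
  n_val <- round_half_up(0.09 * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) {
    stop("n too small: every split must receive at least one sample")
  }

  tier_counts <- apportion(n, tier_mix)
  tiers <- rep(phantom_tiers$tier, times = tier_counts)

  rng <- local_rng(seed)
  tiers <- sample(tiers)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  geom <- data.frame(
    endo_radius = stats::runif(n, 0.10, 0.20) * image_size,
    wall_thickness = stats::runif(n, 0.045, 0.085) * image_size,
    center_row = (image_size - 1) / 2 + stats::runif(n, -0.05, 0.05) * image_size,
    center_col = (image_size - 1) / 2 + stats::runif(n, -0.05, 0.05) * image_size
  )
  split <- sample(rep(c("train", "validation", "test"),
                      times = c(n_train, n_val, n_test)))
  restore_rng(rng)

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(
      image_size = image_size,
      center = c(geom$center_row[i], geom$center_col[i]),
      endo_radius = geom$endo_radius[i],
      wall_thickness = geom$wall_thickness[i],
      tier = tiers[i], seed = sub_seeds[i], ...)
    samples[[i]] <- generate_phantom(sp)
    samples[[i]]$id <- sprintf("phantom%04d", i)
  }

  manifest <- data.frame(
    id = vapply(samples, `[[`, "", "id"),
    split = split, tier = tiers,
    endo_radius = geom$endo_radius,
    wall_thickness = geom$wall_thickness,
    center_row = geom$center_row, center_col = geom$center_col,
    seed = sub_seeds
  )

  structure(list(
    train = samples[split == "train"],
    validation = samples[split == "validation"],
    test = samples[split == "test"],
    manifest = manifest
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples (train %d / validation %d / test %d)\n",
              nrow(x$manifest), length(x$train), length(x$validation),
              length(x$test)))
  print(table(x$manifest$tier))
  invisible(x)
}

#' Write a phantom dataset to disk as NIfTI pairs plus a manifest
#'
#' Each sample is written as `<id>_t1.nii.gz` (float32 map) and
#' `<id>_mask.nii.gz` (uint8 mask), with `manifest.csv` recording split,
#' tier, geometry and per-sample seed.
#'
#' @param ds a `phantom_dataset`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c(ds$train, ds$validation, ds$test)) {
    write_t1_map(s$t1_map, file.path(dir, paste0(s$id, "_t1.nii.gz")))
    write_seg_mask(s$gt_mask, file.path(dir, paste0(s$id, "_mask.nii.gz")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(ds$manifest, path, row.names = FALSE)
  invisible(path)
}
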