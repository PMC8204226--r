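test_that("ground-truth mask equals the exhaustive pixel-scan annulus", {
  # independent oracle: scan every pixel center and test the ring condition
  for (geom in list(c(64, 10, 4), c(64, 14, 6), c(48, 7.5, 3.2), c(33, 5, 2.9))) {
    sp <- phantom_spec(image_size = geom[1], endo_radius = geom[2],
                       wall_thickness = geom[3], tier = "excellent", seed = 1)
    s <- generate_phantom(sp)
    n <- sp$image_size
    expected <- matrix(0L, n, n)
    for (r in 0:(n - 1)) for (c in 0:(n - 1)) {
      d <- sqrt((r - sp$center[1])^2 + (c - sp$center[2])^2)
      expected[r + 1, c + 1] <- as.integer(d >= geom[2] & d < geom[2] + geom[3])
    }
    expect_identical(unclass(s$gt_mask), expected)
    expect_gt(sum(s$gt_mask), 0)
  }
})

test_that("off-center geometry is honoured by the pixel-scan oracle", {
  sp <- phantom_spec(image_size = 64, center = c(28.3, 35.7), endo_radius = 10,
                     wall_thickness = 4, tier = "good", seed = 2)
  s <- generate_phantom(sp)
  n <- 64
  count <- 0L
  for (r in 0:(n - 1)) for (c in 0:(n - 1)) {
    d <- sqrt((r - 28.3)^2 + (c - 35.7)^2)
    count <- count + as.integer(d >= 10 & d < 14)
  }
  expect_identical(sum(s$gt_mask), count)
})

test_that("zero noise leaves the myocardium exactly at its tissue mean", {
  for (tier in phantom_tiers$tier) {
    sp <- phantom_spec(image_size = 48, endo_radius = 8, wall_thickness = 4,
                       tier = tier, noise_sd = 0, artefacts = character(),
                       seed = 3)
    s <- generate_phantom(sp)
    vals <- unclass(s$t1_map)[unclass(s$gt_mask) == 1L]
    expect_true(all(vals == sp$t1_myocardium))
    expect_equal(t1_estimate(s$t1_map, s$gt_mask), sp$t1_myocardium,
                 tolerance = 1e-12)
  }
})

test_that("generation is bit-identical for identical specs", {
  sp <- phantom_spec(image_size = 64, tier = "poor", seed = 99)
  s1 <- generate_phantom(sp)
  s2 <- generate_phantom(sp)
  expect_identical(unclass(s1$t1_map), unclass(s2$t1_map))
  expect_identical(unclass(s1$gt_mask), unclass(s2$gt_mask))
})

test_that("invalid geometry is rejected with an explicit message", {
  expect_error(phantom_spec(image_size = 32, endo_radius = 12,
                            wall_thickness = 6), "annulus does not fit")
  expect_error(phantom_spec(endo_radius = -1), "endo_radius")
  expect_error(phantom_spec(wall_thickness = 0), "wall_thickness")
})

test_that("tier contrast is non-increasing from excellent to poor", {
  for (seed in 1:5) {
    contrasts <- vapply(phantom_tiers$tier, function(tier) {
      sp <- phantom_spec(image_size = 48, endo_radius = 8, wall_thickness = 4,
                         tier = tier, noise_sd = 0, artefacts = character(),
                         seed = seed)
      s <- generate_phantom(sp)
      img <- unclass(s$t1_map)
      d <- sqrt(outer((0:47 - sp$center[1])^2, (0:47 - sp$center[2])^2, `+`))
      abs(mean(img[unclass(s$gt_mask) == 1]) - mean(img[d < 8]))
    }, numeric(1))
    expect_true(all(diff(contrasts) <= 0))
  }
})

test_that("poor-tier phantoms carry at least one artefact effect", {
  # with artefacts unset, poor draws >= 1 artefact: the zero-noise image must
  # differ from an artefact-free render
  sp_art <- phantom_spec(image_size = 48, endo_radius = 8, wall_thickness = 4,
                         tier = "poor", noise_sd = 0, seed = 7)
  sp_clean <- phantom_spec(image_size = 48, endo_radius = 8, wall_thickness = 4,
                           tier = "poor", noise_sd = 0, artefacts = character(),
                           seed = 7)
  expect_false(identical(unclass(generate_phantom(sp_art)$t1_map),
                         unclass(generate_phantom(sp_clean)$t1_map)))
})

test_that("dataset split sizes follow 80/9/11 with half-away-from-zero rounding", {
  ds <- generate_dataset(100, tier_mix = rep(0.25, 4), seed = 1, image_size = 32)
  expect_identical(vapply(ds[c("train", "validation", "test")], length, 1L),
                   c(train = 80L, validation = 9L, test = 11L))

  # clinical-scale count: 2383 maps -> 1906 training samples
  n <- 2383
  expect_identical(floor(0.80 * n + 0.5), 1906)
  m <- generate_dataset(20, seed = 1, image_size = 16)$manifest
  expect_identical(sum(m$split == "train"), as.integer(floor(0.80 * 20 + 0.5)))
})

test_that("tier counts follow the mix by largest-remainder apportionment", {
  ds <- generate_dataset(50, tier_mix = c(0.052, 0.235, 0.653, 0.060),
                         seed = 4, image_size = 32)
  tab <- table(factor(ds$manifest$tier, levels = phantom_tiers$tier))
  # largest remainder on 50 * (0.052, 0.235, 0.653, 0.060) = (2.6, 11.75,
  # 32.65, 3.0): floors (2, 11, 32, 3) leave 2 seats; the two largest
  # remainders (0.75 good, 0.65 acceptable) get them
  expect_identical(as.integer(tab), c(2L, 12L, 33L, 3L))
  expect_identical(sum(tab), 50L)
})

test_that("dataset generation is reproducible and splits partition the data", {
  d1 <- generate_dataset(50, seed = 10, image_size = 32)
  d2 <- generate_dataset(50, seed = 10, image_size = 32)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(unclass(d1$train[[3]]$t1_map), unclass(d2$train[[3]]$t1_map))
  ids <- c(vapply(d1$train, `[[`, "", "id"),
           vapply(d1$validation, `[[`, "", "id"),
           vapply(d1$test, `[[`, "", "id"))
  expect_identical(sort(ids), sort(d1$manifest$id))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("too-small datasets are rejected", {
  expect_error(generate_dataset(5, seed = 1), ">= 10")
  expect_error(generate_dataset(30, tier_mix = c(0.5, 0.5, 0.1, 0.1), seed = 1),
               "sum to 1")
})
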