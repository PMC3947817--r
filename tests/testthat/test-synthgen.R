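small_cfg <- function(...) {
  args <- modifyList(list(n_subjects = 2, samples_per_subject = 4,
                          image_size = c(48, 48), n_vessels = 4, seed = 11),
                     list(...))
  do.call(synth_config, args)
}

test_that("zero vessel depth yields a flat background template", {
  cfg <- small_cfg(vessel_depth = 0)
  tpl <- make_subject_template(cfg, 1)
  expect_equal(tpl, matrix(cfg$background_level, 48, 48))
})

test_that("templates and datasets are pure functions of the config", {
  cfg <- small_cfg(seed = 5)
  expect_identical(make_subject_template(cfg, 2),
                   make_subject_template(cfg, 2))
  d1 <- make_dataset(cfg); d2 <- make_dataset(cfg)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$meta, d2$meta)
  # different subjects get different vessel layouts
  expect_gt(mean(abs(make_subject_template(cfg, 1) -
                     make_subject_template(cfg, 2))), 0.001)
})

test_that("dataset counts and split labels follow the half/half protocol", {
  ds <- make_dataset(small_cfg(n_subjects = 2, samples_per_subject = 12))
  expect_length(ds$images, 24)
  expect_equal(sum(ds$meta$split == "enroll"), 12)
  expect_equal(sum(ds$meta$split == "test"), 12)
  for (s in 1:2) {
    sub <- ds$meta[ds$meta$subject_id == s, ]
    expect_equal(nrow(sub), 12)
    expect_setequal(sub$sample_index, 1:12)
    expect_equal(sub$split, rep(c("enroll", "test"), each = 6))
  }
  expect_error(make_dataset(small_cfg(samples_per_subject = 5)), "even")
})

test_that("without jitter or noise every sample equals its template", {
  cfg <- small_cfg(noise_sd = 0, jitter_shift = 0, jitter_rot = 0,
                   jitter_gain = 0)
  ds <- make_dataset(cfg)
  for (i in seq_along(ds$images)) {
    tpl <- make_subject_template(cfg, ds$meta$subject_id[i])
    expect_identical(ds$images[[i]], tpl)
  }
})

test_that("additive noise matches the folded-normal mean absolute deviation", {
  # E|N(0, sigma)| = sigma * sqrt(2/pi) = 0.0399 for sigma = 0.05
  cfg <- small_cfg(image_size = c(64, 64), noise_sd = 0.05,
                   jitter_shift = 0, jitter_rot = 0, jitter_gain = 0,
                   vessel_depth = 0.3, background_level = 0.6)
  ds <- make_dataset(cfg)
  for (i in seq_along(ds$images)) {
    tpl <- make_subject_template(cfg, ds$meta$subject_id[i])
    mad <- mean(abs(ds$images[[i]] - tpl))
    expect_gt(mad, 0.03); expect_lt(mad, 0.05)
  }
})

test_that("a straight vessel renders the closed-form Gaussian cross-section", {
  sigma <- 2; depth <- 0.5; bg <- 0.85
  ph <- vessel_phantom(c(63, 63), pi / 6, sigma = sigma, depth = depth,
                       background = bg)
  # probe along the perpendicular through the center: x' is the signed
  # perpendicular distance of each pixel from the centerline
  cr <- 32; cc <- 32
  y <- matrix(seq_len(63) - cr, 63, 63)
  x <- matrix(seq_len(63) - cc, 63, 63, byrow = TRUE)
  d <- x * cos(pi / 6) + y * sin(pi / 6)
  expected <- pmin(pmax(bg - depth * exp(-d^2 / sigma^2), 0), 1)
  expect_lt(max(abs(ph - expected)), 0.02)
})

test_that("intra-class pixel distance stays below inter-class distance", {
  ds <- make_dataset(small_cfg(n_subjects = 4, samples_per_subject = 4,
                               n_vessels = 6))
  meta <- ds$meta
  dist_ij <- function(i, j) mean(abs(ds$images[[i]] - ds$images[[j]]))
  intra <- c(); inter <- c()
  for (i in seq_along(ds$images))
    for (j in seq_len(i - 1)) {
      d <- dist_ij(i, j)
      if (meta$subject_id[i] == meta$subject_id[j]) intra <- c(intra, d)
      else inter <- c(inter, d)
    }
  expect_lt(mean(intra), mean(inter))
})

test_that("datasets round-trip through PNG files and the JSON manifest", {
  cfg <- small_cfg(image_size = c(32, 32))
  ds <- make_dataset(cfg)
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  back <- read_dataset(root)
  expect_equal(back$meta$subject_id, ds$meta$subject_id)
  expect_equal(back$meta$split, ds$meta$split)
  # 8-bit quantization at file I/O only
  err <- max(mapply(function(a, b) max(abs(a - b)), ds$images, back$images))
  expect_lt(err, 1 / 255)
})
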