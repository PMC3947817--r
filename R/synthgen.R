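# synthetic palm-vein image generator
#
# Vein cross-sections in NIR palm images are well approximated by (inverted)
# Gaussian profiles, which is exactly the structure the matched-filter bank is
# designed for. The generator renders dark curvilinear ridges with Gaussian
# cross-sections on a brighter background, then produces per-subject sample
# sets under small geometric/intensity jitter plus additive noise.

#' Synthetic dataset configuration
#'
#' Holds every parameter of the synthetic palm-vein generator. The dataset is
#' a pure function of this configuration: the same config (including `seed`)
#' always yields a bit-identical dataset.
#'
#' @param n_subjects number of subjects (each gets its own vessel template).
#' @param samples_per_subject images per subject; must be even for the default
#'   half-enroll / half-test split.
#' @param image_size `c(rows, cols)` of generated images.
#' @param n_vessels vessels rendered per subject template.
#' @param vessel_sigma Gaussian cross-section width (pixels): at perpendicular
#'   distance `d` from a centerline the intensity drops by
#'   `vessel_depth * exp(-d^2 / vessel_sigma^2)`.
#' @param vessel_depth intensity drop at the vessel centerline, in `(0, 1]`
#'   (0 allowed for degenerate test cases).
#' @param background_level background intensity in `(0, 1)`.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param jitter_shift max per-sample translation (pixels, each axis).
#' @param jitter_rot max per-sample rotation (degrees).
#' @param jitter_gain max multiplicative intensity change, gain drawn from
#'   `[1 - jitter_gain, 1 + jitter_gain]`.
#' @param seed integer master seed.
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, samples_per_subject = 4,
#'                     image_size = c(48, 48), seed = 1)
#' ds <- make_dataset(cfg)
#' length(ds$images)
synth_config <- function(n_subjects = 50,
                         samples_per_subject = 12,
                         image_size = c(96, 96),
                         n_vessels = 10,
                         vessel_sigma = 2,
                         vessel_depth = 0.5,
                         background_level = 0.85,
                         noise_sd = 0.05,
                         jitter_shift = 2,
                         jitter_rot = 3,
                         jitter_gain = 0.1,
                         seed = 1) {
  if (!is.numeric(image_size) || length(image_size) != 2 ||
      any(image_size < 8) || any(image_size != round(image_size)))
    stop("`image_size` must be two integers >= 8", call. = FALSE)
  stopifnot_scalar_num(n_subjects, "n_subjects", positive = TRUE)
  stopifnot_scalar_num(samples_per_subject, "samples_per_subject", positive = TRUE)
  stopifnot_scalar_num(n_vessels, "n_vessels", positive = TRUE)
  stopifnot_scalar_num(vessel_sigma, "vessel_sigma", positive = TRUE)
  stopifnot_scalar_num(vessel_depth, "vessel_depth", nonneg = TRUE)
  stopifnot_scalar_num(background_level, "background_level", positive = TRUE)
  if (background_level >= 1) stop("`background_level` must be < 1", call. = FALSE)
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_num(jitter_shift, "jitter_shift", nonneg = TRUE)
  stopifnot_scalar_num(jitter_rot, "jitter_rot", nonneg = TRUE)
  stopifnot_scalar_num(jitter_gain, "jitter_gain", nonneg = TRUE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    samples_per_subject = as.integer(samples_per_subject),
    image_size = as.integer(image_size),
    n_vessels = as.integer(n_vessels),
    vessel_sigma = vessel_sigma, vessel_depth = vessel_depth,
    background_level = background_level, noise_sd = noise_sd,
    jitter_shift = jitter_shift, jitter_rot = jitter_rot,
    jitter_gain = jitter_gain, seed = as.integer(seed)
  ), class = "synth_config")
}

# minimum distance from every pixel center to a polyline (exact point-to-
# segment distances, evaluated only inside a window around each segment)
polyline_distance <- function(size, pts, maxd) {
  nr <- size[1]; nc <- size[2]
  dmin <- matrix(Inf, nr, nc)
  if (nrow(pts) < 2) return(dmin)
  for (s in seq_len(nrow(pts) - 1)) {
    p1 <- pts[s, ]; p2 <- pts[s + 1, ]
    r0 <- max(1L, floor(min(p1[1], p2[1]) - maxd))
    r1 <- min(nr, ceiling(max(p1[1], p2[1]) + maxd))
    c0 <- max(1L, floor(min(p1[2], p2[2]) - maxd))
    c1 <- min(nc, ceiling(max(p1[2], p2[2]) + maxd))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    v <- p2 - p1
    L2 <- sum(v^2)
    dr <- outer(rr - p1[1], rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - p1[2])
    t <- if (L2 > 0) (dr * v[1] + dc * v[2]) / L2 else dr * 0
    t <- pmin(pmax(t, 0), 1)
    d2 <- (dr - t * v[1])^2 + (dc - t * v[2])^2
    dmin[rr, cc] <- pmin(dmin[rr, cc], sqrt(d2))
  }
  dmin
}

# smoothed random-walk centerline: fixed step length, bounded turning angle
random_walk_path <- function(size, step = 1.5, max_turn = 0.25) {
  nr <- size[1]; nc <- size[2]
  n_steps <- ceiling(1.6 * max(nr, nc) / step)
  p <- c(runif(1, 1, nr), runif(1, 1, nc))
  ang <- runif(1, 0, 2 * pi)
  path <- matrix(NA_real_, n_steps + 1, 2)
  path[1, ] <- p
  for (i in seq_len(n_steps)) {
    ang <- ang + runif(1, -max_turn, max_turn)
    p <- p + step * c(cos(ang), sin(ang))
    path[i + 1, ] <- p
  }
  path
}

#' Render one subject's vessel template
#'
#' Draws `n_vessels` smoothed random-walk centerlines on a flat background; at
#' perpendicular distance `d` from the nearest centerline the intensity is
#' reduced by `vessel_depth * exp(-d^2 / vessel_sigma^2)`. Deterministic given
#' `(config$seed, subject_id)`.
#'
#' @param config a [synth_config()].
#' @param subject_id subject index in `1..n_subjects`.
#' @return A `rows x cols` matrix with values in `[0, 1]`.
#' @export
make_subject_template <- function(config, subject_id) {
  stopifnot(inherits(config, "synth_config"))
  if (subject_id < 1 || subject_id > config$n_subjects)
    stop("`subject_id` out of range", call. = FALSE)
  size <- config$image_size
  maxd <- 3.5 * config$vessel_sigma + 1
  dmin <- with_seed(derive_seed(config$seed, subject_id), {
    d <- matrix(Inf, size[1], size[2])
    for (v in seq_len(config$n_vessels)) {
      pts <- random_walk_path(size)
      d <- pmin(d, polyline_distance(size, pts, maxd))
    }
    d
  })
  drop_amt <- ifelse(is.finite(dmin),
                     config$vessel_depth * exp(-dmin^2 / config$vessel_sigma^2), 0)
  clip01(config$background_level - drop_amt)
}

#' Straight-vessel phantom
#'
#' A single straight vessel through the image center with Gaussian
#' cross-section, using the same orientation convention as the matched-filter
#' bank: the vessel runs along direction `(-sin(theta), cos(theta))` in
#' `(x = column, y = row)` coordinates, so a filter built with the same
#' `theta` is perfectly aligned with it.
#'
#' @param size `c(rows, cols)`.
#' @param theta vessel orientation (radians), matched-filter convention.
#' @param sigma Gaussian cross-section width (pixels).
#' @param depth centerline intensity drop.
#' @param background background level.
#' @return Image matrix in `[0, 1]`; attribute `"centerline"` is a logical
#'   matrix marking pixels within half a pixel of the centerline.
#' @export
vessel_phantom <- function(size, theta, sigma = 2, depth = 0.5,
                           background = 0.85) {
  nr <- size[1]; nc <- size[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  y <- matrix(seq_len(nr) - cr, nr, nc)          # row offset
  x <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)  # col offset
  # perpendicular (cross-section) coordinate, as in the filter kernels
  xp <- x * cos(theta) + y * sin(theta)
  img <- clip01(background - depth * exp(-xp^2 / sigma^2))
  attr(img, "centerline") <- abs(xp) <= 0.5
  img
}

#' Generate a labelled synthetic dataset
#'
#' Per subject, `samples_per_subject` perturbed copies of its template:
#' uniform random shift up to `jitter_shift` pixels, rotation up to
#' `jitter_rot` degrees (bilinear resampling, reflective boundary), a
#' multiplicative gain in `[1 - jitter_gain, 1 + jitter_gain]`, plus
#' `N(0, noise_sd^2)` pixel noise, clipped to `[0, 1]`. The first half of each
#' subject's samples is labelled `enroll`, the second half `test`.
#'
#' @param config a [synth_config()]; `samples_per_subject` must be even.
#' @return An object of class `vein_dataset`: a list with `images` (list of
#'   matrices) and `meta` (data.frame with `subject_id`, `sample_index`,
#'   `split`), plus the generating `config`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$samples_per_subject %% 2 != 0)
    stop("`samples_per_subject` must be even for the half/half split",
         call. = FALSE)
  half <- config$samples_per_subject / 2
  images <- vector("list", config$n_subjects * config$samples_per_subject)
  meta <- data.frame(subject_id = integer(0), sample_index = integer(0),
                     split = character(0), stringsAsFactors = FALSE)
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    tpl <- make_subject_template(config, s)
    for (k in seq_len(config$samples_per_subject)) {
      img <- with_seed(derive_seed(config$seed, s, k), {
        rot <- if (config$jitter_rot > 0)
          runif(1, -config$jitter_rot, config$jitter_rot) else 0
        shift <- if (config$jitter_shift > 0)
          runif(2, -config$jitter_shift, config$jitter_shift) else c(0, 0)
        gain <- if (config$jitter_gain > 0)
          runif(1, 1 - config$jitter_gain, 1 + config$jitter_gain) else 1
        out <- affine_warp(tpl, rot, shift) * gain
        if (config$noise_sd > 0)
          out <- out + matrix(rnorm(length(out), 0, config$noise_sd),
                              nrow(out), ncol(out))
        clip01(out)
      })
      idx <- idx + 1L
      images[[idx]] <- img
      meta <- rbind(meta, data.frame(
        subject_id = s, sample_index = k,
        split = if (k <= half) "enroll" else "test",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(images = images, meta = meta, config = config),
            class = "vein_dataset")
}

#' @export
print.vein_dataset <- function(x, ...) {
  cat(sprintf("vein_dataset: %d images, %d subjects, %dx%d px (%d enroll / %d test)\n",
              length(x$images), length(unique(x$meta$subject_id)),
              nrow(x$images[[1]]), ncol(x$images[[1]]),
              sum(x$meta$split == "enroll"), sum(x$meta$split == "test")))
  invisible(x)
}

#' Write a dataset to disk as PNG files plus a JSON manifest
#'
#' Layout: `<root>/<subject_id>/<sample_index>.png` (8-bit grayscale) and
#' `<root>/manifest.json` echoing the configuration and split labels.
#'
#' @param dataset a `vein_dataset`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "vein_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset$meta))
  for (i in seq_len(nrow(dataset$meta))) {
    sdir <- file.path(root, dataset$meta$subject_id[i])
    dir.create(sdir, showWarnings = FALSE)
    paths[i] <- file.path(sdir, sprintf("%02d.png", dataset$meta$sample_index[i]))
    png::writePNG(dataset$images[[i]], paths[i])
  }
  manifest <- list(
    config = unclass(dataset$config),
    files = data.frame(path = paths, dataset$meta, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param root dataset directory containing `manifest.json`.
#' @return A `vein_dataset`.
#' @export
read_dataset <- function(root) {
  manifest <- jsonlite::read_json(file.path(root, "manifest.json"),
                                  simplifyVector = TRUE)
  images <- lapply(manifest$files$path, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  cfg <- do.call(synth_config, manifest$config[names(formals(synth_config))])
  structure(list(images = images,
                 meta = manifest$files[c("subject_id", "sample_index", "split")],
                 config = cfg),
            class = "vein_dataset")
}
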