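# Z-normalization and the two raw feature channels
#
# WLPP raw channel: level-3 approximation coefficients of db2 and sym2,
# flattened row-major, each Z-normalized with statistics fitted on the
# enrollment split only, then concatenated (db2 part first).
#
# LBPV raw channel: LBPV histograms of the enhanced image and of each
# wavelet approximation (the coefficient arrays are min-max scaled to [0,1]
# per image first, so the three histograms live on commensurate intensity
# scales), each Z-normalized on enrollment statistics, concatenated.

#' Fit Z-normalization statistics
#'
#' Per-dimension mean and population standard deviation (denominator `n`),
#' estimated on the enrollment split only so no test information leaks into
#' the normalization. Zero-variance dimensions are flagged and map to 0.
#'
#' @param train numeric matrix, rows = samples.
#' @return Object of class `znorm_stats`: list with `mean`, `sd`, `zero_sd`.
#' @export
znorm_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1) stop("empty training matrix", call. = FALSE)
  mu <- colMeans(train)
  sdv <- sqrt(colMeans(sweep(train, 2, mu)^2))
  structure(list(mean = mu, sd = sdv, zero_sd = sdv <= 1e-12),
            class = "znorm_stats")
}

#' Apply Z-normalization
#'
#' @param x numeric vector or matrix (rows = samples).
#' @param stats a [znorm_fit()] result of matching dimension.
#' @return Normalized vector/matrix; zero-SD dimensions are set to 0.
#' @export
znorm_apply <- function(x, stats) {
  stopifnot(inherits(stats, "znorm_stats"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != length(stats$mean))
    stop("dimension mismatch between input and z-norm statistics",
         call. = FALSE)
  sd_safe <- ifelse(stats$zero_sd, 1, stats$sd)
  out <- sweep(sweep(x, 2, stats$mean), 2, sd_safe, "/")
  out[, stats$zero_sd] <- 0
  if (vec) drop(out) else out
}

# min-max scale a matrix to [0,1]; constant input maps to all zeros
minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-15) return(x * 0)
  (x - rng[1]) / diff(rng)
}

flatten_rowmajor <- function(m) as.vector(t(m))

#' Fit the WLPP raw channel on a list of images
#'
#' Computes the level-`level` approximation of every image for each wavelet,
#' fits per-wavelet Z-normalization on the enrollment rows, and returns the
#' normalized concatenated feature matrix together with the fitted stats.
#'
#' @param images list of image matrices (normally enhanced images).
#' @param spec a [wavelet_spec()].
#' @param enroll logical vector marking enrollment rows.
#' @return List with `features` (matrix, rows = images), `stats` (per-wavelet
#'   `znorm_stats`), and `spec`.
#' @export
wlpp_features <- function(images, spec = wavelet_spec(), enroll) {
  stopifnot(length(enroll) == length(images))
  blocks <- list(); stats <- list()
  for (w in spec$wavelets) {
    raw <- t(vapply(images,
                    function(im) flatten_rowmajor(wavelet_approx(im, w, spec$level)),
                    numeric(length(flatten_rowmajor(
                      wavelet_approx(images[[1]], w, spec$level))))))
    st <- znorm_fit(raw[enroll, , drop = FALSE])
    blocks[[w]] <- znorm_apply(raw, st)
    stats[[w]] <- st
  }
  list(features = do.call(cbind, blocks), stats = stats, spec = spec)
}

#' WLPP raw vector for a single image
#'
#' @param image image matrix (normally an enhanced image).
#' @param spec a [wavelet_spec()].
#' @param stats named list of per-wavelet [znorm_fit()] statistics (as
#'   returned in `wlpp_features()$stats`).
#' @return Numeric feature vector (db2 block then sym2 block).
#' @export
build_wlpp_raw <- function(image, spec = wavelet_spec(), stats) {
  parts <- lapply(spec$wavelets, function(w)
    znorm_apply(flatten_rowmajor(wavelet_approx(image, w, spec$level)),
                stats[[w]]))
  unlist(parts, use.names = FALSE)
}

# the three LBPV source arrays for one image: enhanced image plus min-max
# scaled wavelet approximations
lbpv_sources <- function(image, spec) {
  c(list(enhanced = image),
    stats::setNames(
      lapply(spec$wavelets,
             function(w) minmax01(wavelet_approx(image, w, spec$level))),
      spec$wavelets))
}

#' Fit the LBPV raw channel on a list of images
#'
#' Per image, LBPV histograms of the enhanced image and of each wavelet
#' approximation; per-source Z-normalization fitted on enrollment rows;
#' concatenation in source order (enhanced, then wavelets).
#'
#' @param images list of image matrices (normally enhanced images).
#' @param spec a [wavelet_spec()].
#' @param params an [lbp_params()].
#' @param enroll logical vector marking enrollment rows.
#' @return List with `features` (matrix, `3 * 2^P` columns), `stats`
#'   (per-source `znorm_stats`), `spec`, `params`.
#' @export
lbpv_features <- function(images, spec = wavelet_spec(),
                          params = lbp_params(), enroll) {
  stopifnot(length(enroll) == length(images))
  src_names <- c("enhanced", spec$wavelets)
  hists <- lapply(images, function(im)
    lapply(lbpv_sources(im, spec), function(s) lbpv_histogram(s, params)$bins))
  blocks <- list(); stats <- list()
  for (s in src_names) {
    raw <- t(vapply(hists, function(h) h[[s]], numeric(2^params$P)))
    st <- znorm_fit(raw[enroll, , drop = FALSE])
    blocks[[s]] <- znorm_apply(raw, st)
    stats[[s]] <- st
  }
  list(features = do.call(cbind, blocks), stats = stats,
       spec = spec, params = params)
}

#' LBPV raw vector for a single image
#'
#' @param enhanced enhanced image matrix.
#' @param ll_db2,ll_sym2 the image's wavelet approximation arrays.
#' @param params an [lbp_params()].
#' @param stats named list of per-source [znorm_fit()] statistics with names
#'   `enhanced`, `db2`, `sym2`.
#' @return Numeric vector of length `3 * 2^P`.
#' @export
build_lbpv_raw <- function(enhanced, ll_db2, ll_sym2,
                           params = lbp_params(), stats) {
  srcs <- list(enhanced = enhanced,
               db2 = minmax01(ll_db2), sym2 = minmax01(ll_sym2))
  parts <- lapply(names(srcs), function(s)
    znorm_apply(lbpv_histogram(srcs[[s]], params)$bins, stats[[s]]))
  unlist(parts, use.names = FALSE)
}
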