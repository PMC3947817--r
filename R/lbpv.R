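# local binary patterns and the variance-weighted LBPV histogram
#
# LBP thresholds P circular neighbours at radius R against the center pixel
# and assembles the P bits into a code in [0, 2^P). LBPV replaces the usual
# count-based histogram with a variance-weighted one: the bin of a pixel's
# code accumulates the variance of its ring samples, so high-contrast
# patterns weigh more. No quantization or training is involved.
#
# Neighbour p sits at (-R*sin(2*pi*p/P), R*cos(2*pi*p/P)) relative to the
# center (row, col offsets); off-grid positions are bilinearly interpolated.
# Border pixels without a full ring are skipped, not padded: the valid region
# keeps a margin of ceil(R) + 1 pixels.
#
# The sign function s(x) is 1 for x >= 0; interpolated samples that tie with
# the center only up to floating-point rounding must count as ties, so the
# comparison uses g_p >= g_c - LBP_TIE_EPS.

LBP_TIE_EPS <- 1e-9

#' LBP parameters
#'
#' @param P number of circular neighbours (>= 4).
#' @param R neighbourhood radius in pixels (> 0).
#' @return Object of class `lbp_params`.
#' @export
lbp_params <- function(P = 8L, R = 1) {
  if (P < 4) stop("`P` must be >= 4", call. = FALSE)
  stopifnot_scalar_num(R, "R", positive = TRUE)
  structure(list(P = as.integer(P), R = R), class = "lbp_params")
}

# (row, col) offsets of the P ring positions; exact zeros snapped so axial
# neighbours fall on the integer grid
ring_offsets <- function(params) {
  p <- seq_len(params$P) - 1
  dr <- -params$R * sin(2 * pi * p / params$P)
  dc <- params$R * cos(2 * pi * p / params$P)
  dr[abs(dr) < 1e-12] <- 0
  dc[abs(dc) < 1e-12] <- 0
  cbind(dr = dr, dc = dc)
}

lbp_margin <- function(params) ceiling(params$R) + 1

# interpolated ring samples over the whole valid region:
# array [valid_rows, valid_cols, P]
ring_samples <- function(image, params) {
  m <- lbp_margin(params)
  nr <- nrow(image); nc <- ncol(image)
  if (nr <= 2 * m || nc <= 2 * m)
    stop("image too small for the LBP valid region", call. = FALSE)
  rows <- (m + 1):(nr - m)
  cols <- (m + 1):(nc - m)
  off <- ring_offsets(params)
  out <- array(NA_real_, c(length(rows), length(cols), params$P))
  for (p in seq_len(params$P)) {
    r <- off[p, 1]; c <- off[p, 2]
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    blk <- function(dr, dc) image[rows + dr, cols + dc, drop = FALSE]
    out[, , p] <-
      blk(r0,     c0)     * (1 - fr) * (1 - fc) +
      blk(r0 + 1, c0)     * fr       * (1 - fc) +
      blk(r0,     c0 + 1) * (1 - fr) * fc +
      blk(r0 + 1, c0 + 1) * fr       * fc
  }
  list(samples = out, rows = rows, cols = cols)
}

#' LBP code map over the valid region
#'
#' @param image numeric matrix.
#' @param params an [lbp_params()].
#' @return Integer matrix of LBP codes in `[0, 2^P)` for every valid pixel;
#'   attributes `rows`/`cols` give the valid-region indices.
#' @export
lbp_code_map <- function(image, params = lbp_params()) {
  rs <- ring_samples(image, params)
  gc <- image[rs$rows, rs$cols, drop = FALSE]
  code <- matrix(0, length(rs$rows), length(rs$cols))
  for (p in seq_len(params$P))
    code <- code + (rs$samples[, , p] >= gc - LBP_TIE_EPS) * 2^(p - 1)
  structure(code, rows = rs$rows, cols = rs$cols)
}

#' Ring-variance map over the valid region
#'
#' `VAR = (1/P) * sum_p (g_p - u)^2` with `u` the ring mean, over the same
#' interpolated ring samples as the LBP codes.
#'
#' @inheritParams lbp_code_map
#' @return Numeric matrix of nonnegative variances for every valid pixel.
#' @export
lbp_variance_map <- function(image, params = lbp_params()) {
  rs <- ring_samples(image, params)
  u <- apply(rs$samples, c(1, 2), mean)
  v <- matrix(0, dim(rs$samples)[1], dim(rs$samples)[2])
  for (p in seq_len(params$P)) v <- v + (rs$samples[, , p] - u)^2
  structure(v / params$P, rows = rs$rows, cols = rs$cols)
}

check_valid_pixel <- function(image, pixel, params) {
  m <- lbp_margin(params)
  if (pixel[1] <= m || pixel[1] > nrow(image) - m ||
      pixel[2] <= m || pixel[2] > ncol(image) - m)
    stop("pixel outside the LBP valid region", call. = FALSE)
}

#' LBP code of a single pixel
#'
#' @param image numeric matrix.
#' @param pixel `c(row, col)`, at least `ceil(R) + 1` pixels from every border.
#' @param params an [lbp_params()].
#' @return Integer code in `[0, 2^P)`.
#' @export
lbp_code <- function(image, pixel, params = lbp_params()) {
  check_valid_pixel(image, pixel, params)
  off <- ring_offsets(params)
  g <- bilinear_sample(image, pixel[1] + off[, 1], pixel[2] + off[, 2])
  sum((g >= image[pixel[1], pixel[2]] - LBP_TIE_EPS) * 2^(seq_len(params$P) - 1))
}

#' Ring variance of a single pixel
#'
#' @inheritParams lbp_code
#' @return Nonnegative variance of the P interpolated ring samples.
#' @export
lbp_variance <- function(image, pixel, params = lbp_params()) {
  check_valid_pixel(image, pixel, params)
  off <- ring_offsets(params)
  g <- bilinear_sample(image, pixel[1] + off[, 1], pixel[2] + off[, 2])
  mean((g - mean(g))^2)
}

#' Variance-weighted LBP (LBPV) histogram
#'
#' Bin `k` accumulates the ring variance of every valid pixel whose LBP code
#' equals `k`; the histogram therefore sums exactly to the total variance
#' over the valid region.
#'
#' @inheritParams lbp_code_map
#' @return Object of class `lbpv_histogram`: list with `bins` (length `2^P`)
#'   and `params`.
#' @export
lbpv_histogram <- function(image, params = lbp_params()) {
  codes <- as.vector(lbp_code_map(image, params))
  vars <- as.vector(lbp_variance_map(image, params))
  bins <- numeric(2^params$P)
  acc <- rowsum(vars, codes)
  bins[as.integer(rownames(acc)) + 1] <- acc
  structure(list(bins = bins, params = params), class = "lbpv_histogram")
}
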