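# 2-D discrete wavelet transform (separable, symmetric half-point extension)
#
# Only orthogonal wavelets with short support are needed here: db2 and sym2
# (which share the same four filter taps — Symlets and Daubechies coincide at
# two vanishing moments). The decomposition follows the usual pyramid: filter
# and downsample rows and columns; the LL (approximation) band is cascaded.
# Coefficient counts follow floor((n + L - 1) / 2) per level, the closed form
# for half-point symmetric extension.

#' Wavelet filter taps
#'
#' @param wavelet one of `"db1"`/`"haar"`, `"db2"`, `"sym2"`.
#' @return List with analysis (`dec_lo`, `dec_hi`) and synthesis (`rec_lo`,
#'   `rec_hi`) filters.
#' @export
wavelet_filters <- function(wavelet) {
  lo <- switch(wavelet,
    db1 = , haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = , sym2 = c(-0.12940952255092145, 0.22414386804185735,
                     0.8365163037378079, 0.48296291314469025),
    stop(sprintf("unknown wavelet '%s'", wavelet), call. = FALSE))
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = L, name = wavelet)
}

#' Wavelet feature specification
#'
#' @param wavelets ordered mother-wavelet names whose approximation bands are
#'   concatenated into the global feature (default `c("db2", "sym2")`).
#' @param level decomposition depth (default 3).
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelets = c("db2", "sym2"), level = 3) {
  for (w in wavelets) wavelet_filters(w)  # validate names
  stopifnot_scalar_num(level, "level", positive = TRUE)
  structure(list(wavelets = wavelets, level = as.integer(level),
                 boundary_mode = "symmetric"),
            class = "wavelet_spec")
}

#' Coefficient count per decomposition step
#'
#' Closed form for half-point symmetric extension: `floor((n + L - 1) / 2)`
#' where `L` is the filter length.
#'
#' @param n input length.
#' @param wavelet wavelet name.
#' @return Integer output length.
#' @export
dwt_coeff_len <- function(n, wavelet = "db2") {
  L <- wavelet_filters(wavelet)$length
  floor((n + L - 1) / 2)
}

# one analysis step along the columns of X: half-point symmetric extension,
# causal convolution, downsample. Returns floor((n + L - 1)/2) rows.
dwt_step_cols <- function(X, h) {
  n <- nrow(X); L <- length(h)
  ext <- X[reflect_index(seq(2 - L, n + L - 1), n), , drop = FALSE]
  Y <- stats::filter(ext, h, method = "convolution", sides = 1)
  # valid convolution occupies rows L .. n + 2L - 2; keep even positions
  idx <- seq(L + 1, n + 2 * L - 2, by = 2)
  matrix(Y[idx, ], length(idx), ncol(X))
}

# one synthesis step along columns: upsample, convolve with the synthesis
# filter pair, sum, crop to the target length n
idwt_step_cols <- function(CA, CD, lo_r, hi_r, n) {
  m <- nrow(CA); L <- length(lo_r)
  up <- function(M) {
    U <- matrix(0, 2 * m - 1, ncol(M))
    U[seq(1, 2 * m - 1, by = 2), ] <- M
    U
  }
  conv_full <- function(M, h) {
    # zero-pad both sides so stats::filter yields the full linear convolution
    Mp <- rbind(matrix(0, L - 1, ncol(M)), M, matrix(0, L - 1, ncol(M)))
    Y <- stats::filter(Mp, h, method = "convolution", sides = 1)
    Y[L:(2 * m + 2 * L - 3), , drop = FALSE]
  }
  Y <- conv_full(up(CA), lo_r) + conv_full(up(CD), hi_r)
  Y[(L - 2) + seq_len(n), , drop = FALSE]
}

#' Single-level 2-D DWT
#'
#' @param image numeric matrix.
#' @param wavelet wavelet name.
#' @return List of subbands `LL`, `LH`, `HL`, `HH` (first letter = column
#'   filter, second = row filter).
#' @export
dwt2 <- function(image, wavelet = "db2") {
  f <- wavelet_filters(wavelet)
  lo_c <- dwt_step_cols(image, f$dec_lo)
  hi_c <- dwt_step_cols(image, f$dec_hi)
  t_lo <- function(M, h) t(dwt_step_cols(t(M), h))
  list(LL = t_lo(lo_c, f$dec_lo), LH = t_lo(lo_c, f$dec_hi),
       HL = t_lo(hi_c, f$dec_lo), HH = t_lo(hi_c, f$dec_hi))
}

#' Single-level inverse 2-D DWT
#'
#' @param bands list as returned by [dwt2()].
#' @param wavelet wavelet name.
#' @param size target `c(rows, cols)` of the reconstruction.
#' @return Reconstructed matrix.
#' @export
idwt2 <- function(bands, wavelet = "db2", size) {
  f <- wavelet_filters(wavelet)
  inv_rows <- function(A, D) t(idwt_step_cols(t(A), t(D), f$rec_lo, f$rec_hi,
                                              size[2]))
  lo_c <- inv_rows(bands$LL, bands$LH)
  hi_c <- inv_rows(bands$HL, bands$HH)
  idwt_step_cols(lo_c, hi_c, f$rec_lo, f$rec_hi, size[1])
}

#' Cascaded approximation (LL) coefficients
#'
#' Applies `level` 2-D analysis steps, keeping only the LL band at each step
#' — the multiresolution approximation used as the global vein feature.
#'
#' @param image numeric matrix; must be at least `2^level` in each dimension.
#' @param wavelet wavelet name.
#' @param level decomposition depth.
#' @return Matrix of level-`level` approximation coefficients.
#' @export
wavelet_approx <- function(image, wavelet = "db2", level = 3) {
  if (min(dim(image)) < 2^level)
    stop("image too small for the requested decomposition level", call. = FALSE)
  A <- image
  for (i in seq_len(level)) A <- dwt2(A, wavelet)$LL
  A
}
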