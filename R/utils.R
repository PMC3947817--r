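# shared low-level helpers: seeded evaluation, boundary reflection, bilinear
# sampling and affine warps used by both the generator and the filters

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not perturb the
#' caller's random stream. Used to make generator output a pure function of the
#' configuration.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-(seed, stream) sub-seed, kept < 2^31
derive_seed <- function(seed, a, b = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + as.numeric(a) * 9176 + as.numeric(b) * 7
  as.integer(s %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# half-sample symmetric reflection of arbitrary integer indices into 1..n
# (edge pixel repeated: ... 2 1 | 1 2 ... n | n n-1 ...)
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j >= n, 2 * n - 1 - j, j)
  j + 1
}

# pad a matrix by m pixels on each side with half-sample symmetric reflection
pad_reflect <- function(img, m) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- reflect_index(seq(1 - m, nr + m), nr)
  ci <- reflect_index(seq(1 - m, nc + m), nc)
  img[ri, ci, drop = FALSE]
}

# vectorized bilinear sampling at fractional (row, col) positions with
# reflective boundary handling; r, c same length
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i0 <- reflect_index(r0, nr); i1 <- reflect_index(r0 + 1, nr)
  j0 <- reflect_index(c0, nc); j1 <- reflect_index(c0 + 1, nc)
  img[cbind(i0, j0)] * (1 - fr) * (1 - fc) +
    img[cbind(i1, j0)] * fr * (1 - fc) +
    img[cbind(i0, j1)] * (1 - fr) * fc +
    img[cbind(i1, j1)] * fr * fc
}

# rotate (degrees, about the image center) then translate (rows, cols) an
# image, bilinear resampling, reflective boundary; the inverse map is applied
# so that the OUTPUT pixel grid is sampled from the input
affine_warp <- function(img, rot_deg = 0, shift = c(0, 0)) {
  nr <- nrow(img); nc <- ncol(img)
  if (rot_deg == 0 && all(shift == 0)) return(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- rot_deg * pi / 180
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  # inverse transform: undo translation, then rotate by -th about center
  r1 <- g$r - shift[1] - cr
  c1 <- g$c - shift[2] - cc
  rs <- cos(th) * r1 - sin(th) * c1 + cr
  cs <- sin(th) * r1 + cos(th) * c1 + cc
  matrix(bilinear_sample(img, rs, cs), nr, nc)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
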