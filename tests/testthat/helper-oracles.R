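# independent brute-force oracles: naive per-pixel / per-threshold loops kept
# deliberately separate from the vectorized implementations they check

# bilinear interpolation at one in-range point (no boundary handling needed
# inside the LBP valid region)
bf_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
    img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
}

bf_ring <- function(img, i, j, P, R) {
  vapply(0:(P - 1), function(p) {
    dr <- -R * sin(2 * pi * p / P); dc <- R * cos(2 * pi * p / P)
    dr <- ifelse(abs(dr) < 1e-12, 0, dr)
    dc <- ifelse(abs(dc) < 1e-12, 0, dc)
    bf_bilinear(img, i + dr, j + dc)
  }, numeric(1))
}

# the sign threshold tolerates floating-point ties of interpolated samples,
# part of the operation's definition
bf_lbp_code <- function(img, i, j, P = 8, R = 1) {
  g <- bf_ring(img, i, j, P, R)
  sum((g >= img[i, j] - 1e-9) * 2^(0:(P - 1)))
}

bf_lbp_var <- function(img, i, j, P = 8, R = 1) {
  g <- bf_ring(img, i, j, P, R)
  mean((g - mean(g))^2)
}

# literal double loop over (pixels x codes) accumulating ring variance
bf_lbpv_hist <- function(img, P = 8, R = 1) {
  m <- ceiling(R) + 1
  bins <- numeric(2^P)
  for (i in (m + 1):(nrow(img) - m))
    for (j in (m + 1):(ncol(img) - m)) {
      k <- bf_lbp_code(img, i, j, P, R)
      bins[k + 1] <- bins[k + 1] + bf_lbp_var(img, i, j, P, R)
    }
  bins
}

# naive correlation of a reflectively padded image with a kernel
bf_filter2_reflect <- function(img, k) {
  hw <- (nrow(k) - 1) / 2
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n); ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      for (a in -hw:hw)
        for (b in -hw:hw)
          out[i, j] <- out[i, j] +
            k[a + hw + 1, b + hw + 1] *
            img[refl(i + a, nrow(img)), refl(j + b, ncol(img))]
  out
}

# naive all-thresholds FAR/FRR sweep with the same linear-interpolation EER
# definition, counting with explicit loops
bf_eer <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  far <- vapply(thr, function(t) sum(impostor <= t) / length(impostor),
                numeric(1))
  frr <- vapply(thr, function(t) sum(genuine > t) / length(genuine),
                numeric(1))
  d <- far - frr
  k <- which(d >= 0)[1]
  if (k == 1) { f1 <- 0; r1 <- 1 } else { f1 <- far[k - 1]; r1 <- frr[k - 1] }
  f2 <- far[k]; r2 <- frr[k]
  d1 <- f1 - r1; d2 <- f2 - r2
  alpha <- if (d2 - d1 > 0) -d1 / (d2 - d1) else 0
  100 * (f1 + alpha * (f2 - f1))
}

# naive pairwise distances
bf_distance <- function(test, enroll, metric) {
  out <- matrix(0, nrow(test), nrow(enroll))
  for (i in seq_len(nrow(test)))
    for (j in seq_len(nrow(enroll))) {
      x <- test[i, ]; y <- enroll[j, ]
      out[i, j] <- switch(metric,
        euclidean = sqrt(sum((x - y)^2)),
        manhattan = sum(abs(x - y)),
        cosine = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
        correlation = 1 - cor(x, y))
    }
  out
}

# quick labelled distance matrix from plain matrices
make_dm <- function(values, test_subject, enroll_subject,
                    metric = "euclidean") {
  structure(list(values = values, metric = metric,
                 genuine_mask = outer(test_subject, enroll_subject, "=="),
                 test_subject = test_subject,
                 enroll_subject = enroll_subject,
                 enroll_sample = seq_along(enroll_subject)),
            class = "distance_matrix")
}
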