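test_that("every kernel of the bank is zero-sum at six orientations", {
  for (sigma in c(1.5, 2, 3)) {
    p <- matched_filter_params(sigma = sigma, length = 9)
    bank <- filter_bank(p)
    expect_length(bank$kernels, 6)
    expect_equal(bank$thetas, (0:5) * pi / 6)
    for (k in bank$kernels) expect_lt(abs(sum(k)), 1e-10)
  }
  p <- matched_filter_params(gaussian_convention = "standard")
  expect_lt(abs(sum(build_kernel(p, 0.7))), 1e-10)
})

test_that("kernel symmetries: theta = 0 equals theta = pi and its own flip", {
  p <- matched_filter_params(sigma = 2, length = 9)
  k0 <- build_kernel(p, 0)
  expect_equal(k0, build_kernel(p, pi))
  expect_equal(k0, k0[nrow(k0):1, ])  # reflection across the x-axis
})

test_that("kernel center value equals -1 - m with m the support mean", {
  sigma <- 2; L <- 9
  p <- matched_filter_params(sigma = sigma, length = L)
  k <- build_kernel(p, 0)
  # enumerate the support grid directly: hw = ceil(max(3*sigma, L/2)) = 6
  hw <- 6
  vals <- c()
  for (x in -hw:hw) for (y in -hw:hw)
    if (abs(x) <= 3 * sigma && abs(y) <= L / 2)
      vals <- c(vals, -exp(-x^2 / sigma^2))
  m <- sum(vals) / length(vals)
  expect_equal(k[hw + 1, hw + 1], -1 - m, tolerance = 1e-12)
})

test_that("constant images give zero raw response and an all-zero enhancement", {
  img <- matrix(0.6, 40, 40)
  p <- matched_filter_params()
  r <- matched_filter_response(img, p)$response
  expect_lt(max(abs(r)), 1e-10)
  expect_warning(out <- enhance_image(img, p), "constant")
  expect_equal(out, matrix(0, 40, 40))
})

test_that("raw responses are linear in the image and ignore constants", {
  set.seed(42)
  img <- matrix(runif(40 * 40), 40, 40)
  p <- matched_filter_params()
  r <- matched_filter_response(img, p)
  r_shift <- matched_filter_response(img + 0.3, p)
  expect_lt(max(abs(r$response - r_shift$response)), 1e-8)
  # homogeneity of each orientation's raw response (max is not linear, the
  # per-orientation responses are)
  r_scaled <- matched_filter_response(2.5 * img, p)
  for (j in 1:6)
    expect_equal(r_scaled$per_theta[[j]], 2.5 * r$per_theta[[j]],
                 tolerance = 1e-10)
})

test_that("FFT correlation with reflective padding matches a naive loop", {
  set.seed(7)
  img <- matrix(runif(12 * 12), 12, 12)
  p <- matched_filter_params(sigma = 0.8, length = 3)
  for (th in c(0, pi / 3)) {
    k <- build_kernel(p, th)
    expect_equal(veinverify:::conv2_reflect(img, k)[[1]],
                 bf_filter2_reflect(img, k), tolerance = 1e-10)
  }
})

test_that("the matched orientation wins on centerline pixels", {
  p <- matched_filter_params(sigma = 2, length = 9)
  ph <- vessel_phantom(c(64, 64), 2 * pi / 6, sigma = 2)
  om <- orientation_map(ph, p)
  cl <- attr(ph, "centerline")
  inner <- matrix(FALSE, 64, 64); inner[11:54, 11:54] <- TRUE
  expect_gte(mean(om[cl & inner] == 2), 0.95)
  # rotating the phantom by pi/6 shifts the winning orientation by one
  ph2 <- vessel_phantom(c(64, 64), 3 * pi / 6, sigma = 2)
  om2 <- orientation_map(ph2, p)
  cl2 <- attr(ph2, "centerline")
  expect_gte(mean(om2[cl2 & inner] == 3), 0.90)
})

test_that("centerline responses dominate background responses", {
  p <- matched_filter_params(sigma = 2, length = 9)
  ph <- vessel_phantom(c(64, 64), pi / 6, sigma = 2)
  r <- matched_filter_response(ph, p)$response
  cl <- attr(ph, "centerline")
  # background: pixels far from the vessel
  y <- matrix(seq_len(64) - 32.5, 64, 64)
  x <- matrix(seq_len(64) - 32.5, 64, 64, byrow = TRUE)
  far <- abs(x * cos(pi / 6) + y * sin(pi / 6)) > 10
  expect_gt(median(r[cl]), median(r[far]))
})

test_that("multi-scale and parameter validation behave", {
  expect_error(matched_filter_params(sigma = -1), "sigma")
  expect_error(matched_filter_response(matrix(numeric(0), 0, 0),
                                       matched_filter_params()), "empty")
  p <- matched_filter_params(sigmas = c(1.5, 2.5))
  ph <- vessel_phantom(c(48, 48), 0, sigma = 2)
  out <- enhance_image(ph, p)
  expect_equal(range(out), c(0, 1))
})
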