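test_that("perfectly separated scores give zero EER", {
  ev <- far_frr(genuine = c(0.1, 0.2), impostor = c(0.8, 0.9))
  expect_equal(ev$eer, 0)
  expect_true(all(diff(ev$far) >= 0))
  expect_true(all(diff(ev$frr) <= 0))
  expect_error(far_frr(numeric(0), 1), "empty")
})

test_that("EER matches the brute-force threshold sweep on random multisets", {
  set.seed(55)
  for (r in 1:20) {
    n <- sample(3:30, 1)
    # duplicate-heavy integer scores exercise tie handling
    g <- sample(0:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
    i <- sample(2:10, n, replace = TRUE)
    expect_equal(compute_eer(g, i), bf_eer(g, i), tolerance = 1e-12)
  }
  # the fully inverted singleton case is defined by the same sweep
  expect_equal(compute_eer(0.3, 0.1), bf_eer(0.3, 0.1))
})

test_that("exchangeable genuine and impostor scores sit at 50% EER", {
  set.seed(202)
  g <- rnorm(1e4); i <- rnorm(1e4)
  expect_lt(abs(compute_eer(g, i) - 50), 2)
})

test_that("EER is invariant under strictly monotone score transforms", {
  set.seed(66)
  g <- rnorm(200, 0); i <- rnorm(300, 1)
  e0 <- compute_eer(g, i)
  expect_equal(compute_eer(exp(g), exp(i)), e0, tolerance = 1e-10)
  expect_equal(compute_eer(3 * g + 7, 3 * i + 7), e0, tolerance = 1e-10)
})

test_that("min-max normalization maps to [0,1] and preserves EER", {
  expect_equal(minmax_normalize(matrix(c(1, 3, 5), 1)),
               matrix(c(0, 0.5, 1), 1))
  set.seed(10)
  v <- matrix(runif(36, 2, 9), 6, 6)
  dm <- make_dm(v, rep(1:3, each = 2), rep(1:3, each = 2))
  nd <- minmax_normalize(dm)
  expect_equal(range(nd$values), c(0, 1))
  s0 <- verification_scores(dm); s1 <- verification_scores(nd)
  expect_equal(compute_eer(s1$genuine, s1$impostor),
               compute_eer(s0$genuine, s0$impostor), tolerance = 1e-10)
  expect_warning(minmax_normalize(matrix(2, 3, 3)), "constant")
})

test_that("fusing a channel with itself reproduces its EER at every weight", {
  set.seed(11)
  v <- matrix(runif(64), 8, 8)
  subs <- rep(1:4, each = 2)
  d1 <- make_dm(v, subs, subs)
  fus <- fuse_and_search(d1, d1, step = 0.25)
  s <- verification_scores(d1)
  e <- compute_eer(s$genuine, s$impostor)
  expect_true(all(abs(fus$grid$eer - e) < 1e-10))
})

test_that("fused EER never exceeds either single-channel EER", {
  set.seed(121)
  subs <- rep(1:5, each = 2)
  for (r in 1:5) {
    d1 <- make_dm(matrix(runif(100), 10, 10), subs, subs)
    d2 <- make_dm(matrix(runif(100), 10, 10), subs, subs)
    fus <- fuse_and_search(d1, d2, step = 0.05)
    ends <- c(fus$grid$eer[1], fus$grid$eer[nrow(fus$grid)])
    expect_lte(fus$eer, min(ends) + 1e-12)
  }
})

test_that("complementary channels are fused at an interior weight", {
  # channel 1 separates subjects 1-2 and inverts 3-4; channel 2 mirrors it
  subs <- 1:4
  base <- matrix(0.55, 4, 4)
  d1v <- base; d2v <- base
  for (s in 1:4) {
    if (s <= 2) { d1v[s, s] <- 0; d2v[s, s] <- 0.9 }
    else        { d1v[s, s] <- 0.9; d2v[s, s] <- 0 }
  }
  d1 <- make_dm(d1v, subs, subs); d2 <- make_dm(d2v, subs, subs)
  fus <- fuse_and_search(d1, d2, step = 0.01)
  expect_gt(fus$weight, 0); expect_lt(fus$weight, 1)
  ends <- c(fus$grid$eer[1], fus$grid$eer[nrow(fus$grid)])
  expect_lt(fus$eer, min(ends))
})

test_that("min-per-claim scoring reduces to per-subject minima", {
  v <- rbind(c(0.1, 0.4, 0.9, 0.8),
             c(0.7, 0.6, 0.2, 0.3))
  dm <- make_dm(v, c(1, 2), c(1, 1, 2, 2))
  s <- verification_scores(dm, "min_per_claim")
  expect_setequal(s$genuine, c(0.1, 0.2))
  expect_setequal(s$impostor, c(0.8, 0.6))
})
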