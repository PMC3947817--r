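test_that("simple weights are a symmetric 0/1 matrix with zero diagonal", {
  set.seed(3)
  X <- matrix(rnorm(20 * 4), 20, 4)
  W <- build_graph(X, lpp_config(k = 3, weight = "simple"))
  expect_true(all(W %in% c(0, 1)))
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 20))
})

test_that("duplicate points connected by the heat kernel get weight one", {
  X <- rbind(c(1, 1), c(1, 1), c(5, 5))
  W <- build_graph(X, lpp_config(k = 1, weight = "heat", t = 2))
  expect_equal(W[1, 2], 1)  # exp(0)
})

test_that("OR-symmetrized kNN on collinear points gives the expected edges", {
  X <- matrix(c(0, 1, 10), 3, 1)
  W <- build_graph(X, lpp_config(k = 1, weight = "simple"))
  # 1's NN is 2; 2's NN is 1; 3's NN is 2 -> edges {1-2, 2-3}
  expect_equal(W[1, 2], 1); expect_equal(W[2, 3], 1)
  expect_equal(W[1, 3], 0)
  expect_error(build_graph(X, lpp_config(k = 3)), "smaller")
})

test_that("epsilon graph connects pairs below the squared threshold", {
  X <- matrix(c(0, 1, 10), 3, 1)
  W <- build_graph(X, lpp_config(graph = "epsilon", epsilon = 2,
                                 weight = "simple"))
  expect_equal(W[1, 2], 1); expect_equal(W[1, 3], 0); expect_equal(W[2, 3], 0)
})

test_that("fitted eigenpairs satisfy the generalized eigenproblem", {
  set.seed(9)
  X <- matrix(rnorm(40 * 10), 40, 10)
  m <- lpp_fit(X, lpp_config(k = 4, l = 5, pca_keep = 1))
  for (i in seq_len(m$l)) {
    a <- m$A[, i]
    res <- sqrt(sum((m$gen_A %*% a - m$eigenvalues[i] * (m$gen_B %*% a))^2)) /
      sqrt(sum(a^2))
    expect_lt(res, 1e-6)
  }
  expect_true(all(m$all_eigenvalues >= -1e-10))
  # transforming the training matrix reproduces the fit-time embedding
  expect_equal(lpp_transform(m, X), m$Y_train, tolerance = 1e-10)
})

test_that("two well-separated clusters are linearly separated in 1-D", {
  set.seed(5)
  X <- rbind(matrix(rnorm(30 * 10, 0, 0.5), 30, 10),
             matrix(rnorm(30 * 10, 8, 0.5), 30, 10))
  m <- lpp_fit(X, lpp_config(k = 5, l = 1))
  y <- drop(m$Y_train)
  lab <- rep(c(1, 2), each = 30)
  side <- y > mean(range(y))
  errs <- min(sum(side != (lab == 1)), sum(side != (lab == 2)))
  expect_equal(errs, 0)
})

test_that("the embedding is linear in the centered input", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- lpp_fit(X, lpp_config(k = 3, l = 2))
  mu <- m$center
  x <- X[4, ]
  expect_equal(lpp_transform(m, mu + 3 * (x - mu)),
               3 * lpp_transform(m, x) - 2 * lpp_transform(m, mu),
               tolerance = 1e-8)
  expect_error(lpp_transform(m, rnorm(5)), "dimension")
})

test_that("a noisy 1-D manifold in 20-D is recovered by the 1-D embedding", {
  set.seed(17)
  n <- 80
  t_par <- sort(runif(n, 0, 1))
  B <- matrix(rnorm(20 * 2), 20, 2)
  curve <- cbind(t_par, t_par^2) %*% t(B)
  X <- curve + matrix(rnorm(n * 20, 0, 0.01), n, 20)
  m <- lpp_fit(X, lpp_config(k = 6, l = 1))
  rho <- suppressWarnings(cor(drop(m$Y_train), t_par, method = "spearman"))
  expect_gt(abs(rho), 0.9)
})

test_that("the embedding is invariant to sample order up to column signs", {
  set.seed(23)
  X <- matrix(rnorm(35 * 8), 35, 8)
  cfg <- lpp_config(k = 4, l = 3)
  m1 <- lpp_fit(X, cfg)
  perm <- sample(nrow(X))
  m2 <- lpp_fit(X[perm, ], cfg)
  Y1 <- lpp_transform(m1, X)
  Y2 <- lpp_transform(m2, X)
  for (j in 1:3)
    expect_lt(min(max(abs(Y1[, j] - Y2[, j])), max(abs(Y1[, j] + Y2[, j]))),
              1e-6 * max(1, max(abs(Y1[, j]))))
})

test_that("each extra graph component contributes a zero eigenvalue", {
  # two clusters too far apart for k = 2 to bridge
  set.seed(2)
  X <- rbind(matrix(rnorm(10 * 3, 0, 0.1), 10, 3),
             matrix(rnorm(10 * 3, 50, 0.1), 10, 3))
  W <- build_graph(X, lpp_config(k = 2, weight = "simple"))
  expect_equal(veinverify:::components_count(W), 2)
  L <- graph_laplacian(W)$L
  ev <- sort(eigen(L, symmetric = TRUE)$values)
  expect_lt(abs(ev[1]), 1e-8)
  expect_lt(abs(ev[2]), 1e-8)
  expect_gt(ev[3], 1e-8)
  # fitting on a disconnected graph still works and reports the components;
  # the smallest generalized eigenvalue (cluster-separating direction) is
  # far below the rest of the spectrum
  expect_message(
    m <- lpp_fit(X, lpp_config(k = 2, weight = "simple", l = 2, pca_keep = 1)),
    "2 connected components")
  expect_lt(m$eigenvalues[1], 1e-3 * m$eigenvalues[2])
})
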