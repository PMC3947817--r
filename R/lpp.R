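# locality preserving projections
#
# LPP finds a linear map that keeps neighbouring samples close: build a
# neighbourhood graph on the training samples, weight its edges, and solve
# the generalized eigenproblem
#
#     X L X^T a = lambda X D X^T a,
#
# where W is the (symmetric) edge-weight matrix, D = diag(colSums(W)) and
# L = D - W is the graph Laplacian. The embedding keeps the eigenvectors of
# the l smallest eigenvalues. A PCA pre-projection makes X D X^T
# nonsingular, the standard practice in the Laplacian-embedding lineage.

#' LPP configuration
#'
#' @param graph `"knn"` (OR-symmetrized k-nearest-neighbour graph) or
#'   `"epsilon"` (connect pairs with squared distance below `epsilon`).
#' @param k neighbours for the knn graph.
#' @param epsilon squared-distance threshold for the epsilon graph.
#' @param weight `"heat"` for `exp(-||xi - xj||^2 / t)` edge weights or
#'   `"simple"` for 0/1 weights.
#' @param t heat-kernel bandwidth; `"auto"` uses the mean squared pairwise
#'   training distance (scale-free default).
#' @param l embedding dimension; default `min(100, rank)` chosen at fit time.
#' @param pca_keep fraction of variance retained by the PCA pre-projection.
#' @return Object of class `lpp_config`.
#' @export
lpp_config <- function(graph = c("knn", "epsilon"), k = 5L, epsilon = NULL,
                       weight = c("heat", "simple"), t = "auto",
                       l = NULL, pca_keep = 0.98) {
  graph <- match.arg(graph)
  weight <- match.arg(weight)
  if (graph == "epsilon" && is.null(epsilon))
    stop("`epsilon` required for the epsilon graph", call. = FALSE)
  if (!identical(t, "auto")) stopifnot_scalar_num(t, "t", positive = TRUE)
  if (pca_keep <= 0 || pca_keep > 1)
    stop("`pca_keep` must be in (0, 1]", call. = FALSE)
  structure(list(graph = graph, k = as.integer(k), epsilon = epsilon,
                 weight = weight, t = t, l = l, pca_keep = pca_keep),
            class = "lpp_config")
}

# squared Euclidean distance matrix between rows
sqdist <- function(X) {
  n2 <- rowSums(X^2)
  d2 <- outer(n2, n2, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' Build the neighbourhood weight matrix
#'
#' Nodes i and j are connected if i is among the k nearest neighbours of j
#' or vice versa (knn graph), or if `||xi - xj||^2 < epsilon` (epsilon
#' graph). Connected pairs get heat-kernel or unit weights; the diagonal is
#' zero and W is symmetric.
#'
#' @param X numeric matrix, rows = samples.
#' @param cfg an [lpp_config()].
#' @return Symmetric `m x m` weight matrix (attribute `"t"` carries the heat
#'   bandwidth actually used).
#' @export
build_graph <- function(X, cfg = lpp_config()) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2) stop("need at least 2 samples", call. = FALSE)
  d2 <- sqdist(X)
  if (cfg$graph == "knn") {
    if (cfg$k >= m) stop("`k` must be smaller than the number of samples",
                         call. = FALSE)
    adj <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      nb <- order(d2[i, ])[-1][seq_len(cfg$k)]  # drop self
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
  } else {
    adj <- d2 < cfg$epsilon
    diag(adj) <- FALSE
  }
  if (cfg$weight == "heat") {
    t_used <- if (identical(cfg$t, "auto")) mean(d2[upper.tri(d2)]) else cfg$t
    W <- ifelse(adj, exp(-d2 / t_used), 0)
  } else {
    t_used <- NA_real_
    W <- adj * 1
  }
  diag(W) <- 0
  attr(W, "t") <- t_used
  W
}

#' Graph Laplacian pieces
#'
#' @param W symmetric weight matrix.
#' @return List with `D` (vector of degree sums `D_ii = sum_j W_ji`) and `L`
#'   (Laplacian matrix `D - W`).
#' @export
graph_laplacian <- function(W) {
  D <- colSums(W)
  L <- diag(D) - W
  list(D = D, L = L)
}

#' Fit a locality preserving projection
#'
#' The neighbourhood graph is built on the input features; the generalized
#' eigenproblem is solved on PCA-pre-projected, centered data via a Cholesky
#' reduction to a symmetric standard eigenproblem. Eigenvectors are kept in
#' ascending eigenvalue order and each column's sign is fixed so its
#' largest-magnitude entry is positive.
#'
#' @param X numeric matrix of training samples (rows).
#' @param cfg an [lpp_config()].
#' @return Object of class `lpp_model`: `center`, `pre_proj` (PCA basis),
#'   `A` (eigenvector matrix, `q x l`), `eigenvalues` (ascending), `t`,
#'   `cfg`, and the training embedding `Y_train`.
#' @export
lpp_fit <- function(X, cfg = lpp_config()) {
  X <- as.matrix(X)
  m <- nrow(X)
  W <- build_graph(X, cfg)
  gl <- graph_laplacian(W)
  if (any(gl$D == 0))
    warning("isolated node(s) in the neighbourhood graph")
  n_comp <- components_count(W)
  if (n_comp > 1)
    message(sprintf("neighbourhood graph has %d connected components", n_comp))

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  var_expl <- sv$d^2 / sum(sv$d^2)
  q <- which(cumsum(var_expl) >= cfg$pca_keep - 1e-12)[1]
  if (is.na(q)) q <- length(var_expl)
  q <- min(q, sum(sv$d > max(sv$d) * 1e-10), m - 1)
  P <- sv$v[, seq_len(q), drop = FALSE]
  Z <- Xc %*% P

  A_mat <- crossprod(Z, gl$L %*% Z)
  B_mat <- crossprod(Z, gl$D * Z)
  A_mat <- (A_mat + t(A_mat)) / 2
  B_mat <- (B_mat + t(B_mat)) / 2
  R <- tryCatch(chol(B_mat), error = function(e)
    stop(paste("X D X^T is singular after pre-projection;",
               "lower `l` or `pca_keep`"), call. = FALSE))
  # C = R^{-T} A R^{-1}, standard symmetric problem
  S <- forwardsolve(t(R), A_mat)
  C <- t(forwardsolve(t(R), t(S)))
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ord <- rev(seq_along(eg$values))  # ascending
  vals <- eg$values[ord]
  vecs <- backsolve(R, eg$vectors[, ord, drop = FALSE])

  l <- cfg$l
  if (is.null(l)) {
    l <- min(100L, q, m - 1L)
    if (!is.null(cfg$l_max)) l <- min(l, cfg$l_max)  # caller-provided cap
  }
  if (l > q) stop("`l` exceeds the pre-projected rank", call. = FALSE)
  A <- vecs[, seq_len(l), drop = FALSE]
  for (j in seq_len(ncol(A)))
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]

  model <- structure(list(center = mu, pre_proj = P,
                          A = A, eigenvalues = vals[seq_len(l)],
                          all_eigenvalues = vals,
                          gen_A = A_mat, gen_B = B_mat,
                          t = attr(W, "t"), cfg = cfg, l = l, q = q),
                     class = "lpp_model")
  model$Y_train <- lpp_transform(model, X)
  model
}

# connected components of the weighted graph (BFS on the adjacency pattern)
components_count <- function(W) {
  m <- nrow(W)
  seen <- logical(m)
  n <- 0L
  for (s in seq_len(m)) {
    if (seen[s]) next
    n <- n + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  n
}

#' Project samples through a fitted LPP model
#'
#' `y = A^T P^T (x - mu)`: centering, PCA pre-projection, then the LPP
#' eigenvector map. Deterministic and linear in the centered input.
#'
#' @param model an [lpp_fit()] result.
#' @param X numeric vector or matrix (rows = samples) of the training
#'   dimensionality.
#' @return Embedding matrix (rows = samples, `l` columns), or a vector for
#'   vector input.
#' @export
lpp_transform <- function(model, X) {
  stopifnot(inherits(model, "lpp_model"))
  vec <- is.null(dim(X))
  X <- if (vec) matrix(X, 1) else as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("dimension mismatch with the fitted model", call. = FALSE)
  Y <- (sweep(X, 2, model$center) %*% model$pre_proj) %*% model$A
  if (vec) drop(Y) else Y
}

#' @export
print.lpp_model <- function(x, ...) {
  cat(sprintf("lpp_model: %d -> %d dims (PCA rank %d), %s graph, %s weights\n",
              length(x$center), x$l, x$q, x$cfg$graph, x$cfg$weight))
  invisible(x)
}
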