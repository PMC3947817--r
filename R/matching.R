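# nearest-neighbour matching: test x enrolled distance matrices under four
# metrics, with genuine/impostor pair labels for verification scoring

#' Test-versus-enrolled distance matrix
#'
#' Metrics: `euclidean` `||y - x||_2`; `manhattan` `sum |y - x|`; `cosine`
#' `1 - (y.x)/(||y|| ||x||)`; `correlation` `1 - Pearson(y, x)`. A zero-norm
#' (or constant, for correlation) vector makes the angular metrics undefined;
#' such entries are set to 1 with a warning.
#'
#' @param test,enroll numeric matrices with equal column count (rows =
#'   samples).
#' @param metric one of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"correlation"`.
#' @param test_subject,enroll_subject integer subject labels per row, used to
#'   build the genuine/impostor mask.
#' @param enroll_sample optional sample indices of enrolled rows (used for
#'   deterministic tie-breaking in [nn_identify()]).
#' @return Object of class `distance_matrix`: list with `values`
#'   (`n_test x n_enroll`), `metric`, `genuine_mask`, and the label vectors.
#' @export
distance_matrix <- function(test, enroll,
                            metric = c("euclidean", "manhattan", "cosine",
                                       "correlation"),
                            test_subject = NULL, enroll_subject = NULL,
                            enroll_sample = NULL) {
  metric <- match.arg(metric)
  test <- as.matrix(test); enroll <- as.matrix(enroll)
  if (ncol(test) != ncol(enroll))
    stop("feature dimensions differ", call. = FALSE)
  nt <- nrow(test); ne <- nrow(enroll)
  vals <- switch(metric,
    euclidean = {
      d2 <- outer(rowSums(test^2), rowSums(enroll^2), "+") -
        2 * tcrossprod(test, enroll)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      m <- matrix(0, nt, ne)
      for (j in seq_len(ne))
        m[, j] <- rowSums(abs(sweep(test, 2, enroll[j, ])))
      m
    },
    cosine = angular_distance(test, enroll, center = FALSE),
    correlation = angular_distance(test, enroll, center = TRUE))
  gm <- if (!is.null(test_subject) && !is.null(enroll_subject))
    outer(test_subject, enroll_subject, "==") else NULL
  structure(list(values = vals, metric = metric, genuine_mask = gm,
                 test_subject = test_subject, enroll_subject = enroll_subject,
                 enroll_sample = enroll_sample),
            class = "distance_matrix")
}

angular_distance <- function(test, enroll, center) {
  if (center) {
    test <- test - rowMeans(test)
    enroll <- enroll - rowMeans(enroll)
  }
  nt <- sqrt(rowSums(test^2)); ne <- sqrt(rowSums(enroll^2))
  if (any(nt < 1e-300) || any(ne < 1e-300))
    warning("zero-norm vector(s); affected distances set to 1")
  nts <- ifelse(nt < 1e-300, 1, nt)
  nes <- ifelse(ne < 1e-300, 1, ne)
  d <- 1 - tcrossprod(test / nts, enroll / nes)
  d[nt < 1e-300, ] <- 1
  d[, ne < 1e-300] <- 1
  d
}

#' Nearest-neighbour identification
#'
#' Each test sample is assigned the subject of its globally nearest enrolled
#' sample; ties are broken by the lowest subject id, then the lowest sample
#' index.
#'
#' @param d a [distance_matrix()] with subject labels.
#' @return Integer vector of predicted subject ids, one per test row.
#' @export
nn_identify <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (is.null(d$enroll_subject) || ncol(d$values) == 0)
    stop("empty or unlabelled gallery", call. = FALSE)
  samp <- if (is.null(d$enroll_sample)) seq_len(ncol(d$values))
          else d$enroll_sample
  ord <- order(d$enroll_subject, samp)
  vals <- d$values[, ord, drop = FALSE]
  d$enroll_subject[ord][max.col(-vals, ties.method = "first")]
}
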