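# verification evaluation: FAR/FRR sweeps, EER, score normalization and
# weighted-sum fusion of two distance channels
#
# Scores are dissimilarities (lower = better match). Sweeping a decision
# threshold tau over the observed scores:
#   FAR(tau) = fraction of impostor scores <= tau   (nondecreasing in tau)
#   FRR(tau) = fraction of genuine scores  > tau    (nonincreasing in tau)
# The equal error rate is read off at the FAR - FRR sign change by linear
# interpolation, and reported in percent.

#' Genuine / impostor scores from a distance matrix
#'
#' `all_pairs` (default): every (test, enrolled-same-subject) distance is a
#' genuine score and every cross-subject distance an impostor score.
#' `min_per_claim`: per (test sample, claimed subject), the minimum distance
#' over that subject's enrolled samples.
#'
#' @param d a [distance_matrix()] with a genuine mask.
#' @param rule `"all_pairs"` or `"min_per_claim"`.
#' @return List with numeric vectors `genuine` and `impostor`.
#' @export
verification_scores <- function(d, rule = c("all_pairs", "min_per_claim")) {
  rule <- match.arg(rule)
  stopifnot(inherits(d, "distance_matrix"), !is.null(d$genuine_mask))
  if (rule == "all_pairs")
    return(list(genuine = d$values[d$genuine_mask],
                impostor = d$values[!d$genuine_mask]))
  subs <- sort(unique(d$enroll_subject))
  gen <- c(); imp <- c()
  for (s in subs) {
    cols <- d$enroll_subject == s
    mins <- apply(d$values[, cols, drop = FALSE], 1, min)
    same <- d$test_subject == s
    gen <- c(gen, mins[same]); imp <- c(imp, mins[!same])
  }
  list(genuine = gen, impostor = imp)
}

#' FAR/FRR curves and equal error rate
#'
#' @param genuine,impostor numeric score vectors (lower = better match).
#' @return Object of class `eval_result`: `thresholds`, `far`, `frr` (rates
#'   in `[0, 1]`), `eer` (percent), `eer_threshold`, and `roc`
#'   (data.frame of FAR and 1 - FRR).
#' @export
far_frr <- function(genuine, impostor) {
  if (!length(genuine) || !length(impostor))
    stop("empty score list", call. = FALSE)
  thr <- sort(unique(c(genuine, impostor)))
  gs <- sort(genuine); is <- sort(impostor)
  far <- findInterval(thr, is) / length(is)
  frr <- 1 - findInterval(thr, gs) / length(gs)
  e <- eer_from_curves(thr, far, frr)
  structure(list(thresholds = thr, far = far, frr = frr,
                 eer = 100 * e$rate, eer_threshold = e$threshold,
                 roc = data.frame(far = far, tar = 1 - frr)),
            class = "eval_result")
}

# locate the FAR - FRR sign change and linearly interpolate both curves;
# a virtual operating point (FAR = 0, FRR = 1) below the smallest threshold
# anchors the sweep
eer_from_curves <- function(thr, far, frr) {
  d <- far - frr
  k <- which(d >= 0)[1]
  if (is.na(k)) return(list(rate = far[length(far)], threshold = thr[length(thr)]))
  if (k == 1) { f1 <- 0; r1 <- 1; t1 <- thr[1] } else {
    f1 <- far[k - 1]; r1 <- frr[k - 1]; t1 <- thr[k - 1]
  }
  f2 <- far[k]; r2 <- frr[k]; t2 <- thr[k]
  d1 <- f1 - r1; d2 <- f2 - r2
  alpha <- if (d2 - d1 > 0) -d1 / (d2 - d1) else 0
  list(rate = f1 + alpha * (f2 - f1), threshold = t1 + alpha * (t2 - t1))
}

#' Equal error rate of a genuine/impostor score split
#'
#' @inheritParams far_frr
#' @return EER in percent.
#' @export
compute_eer <- function(genuine, impostor) far_frr(genuine, impostor)$eer

#' Min-max normalize a distance matrix
#'
#' Maps all entries to `[0, 1]` by `(d - min) / (max - min)`; a strictly
#' monotone map, so single-channel EER is unchanged. A constant matrix maps
#' to all zeros with a warning.
#'
#' @param d a [distance_matrix()] or plain numeric matrix.
#' @return Same type as the input, normalized.
#' @export
minmax_normalize <- function(d) {
  v <- if (inherits(d, "distance_matrix")) d$values else d
  rng <- range(v)
  if (diff(rng) < 1e-15) {
    warning("constant distance matrix; normalizing to zeros")
    v <- v * 0
  } else v <- (v - rng[1]) / diff(rng)
  if (inherits(d, "distance_matrix")) { d$values <- v; d } else v
}

#' Weighted-sum fusion with exhaustive weight search
#'
#' Both channels are min-max normalized; the fused matrix is
#' `w * d1 + (1 - w) * d2` and `w` is searched over `{0, step, ..., 1}` for
#' the smallest EER (ties: smallest `w`). Because the endpoints are in the
#' grid, the fused EER never exceeds either single-channel EER.
#'
#' @param d1,d2 [distance_matrix()] objects of equal shape and genuine mask.
#' @param step weight grid step.
#' @param rule score pairing rule, see [verification_scores()].
#' @return Object of class `fusion_result`: `weight`, `eer` (percent),
#'   `eval` (the [far_frr()] result at the optimum), `fused`
#'   (the fused `distance_matrix`), and `grid` (data.frame of w, eer).
#' @export
fuse_and_search <- function(d1, d2, step = 0.01,
                            rule = c("all_pairs", "min_per_claim")) {
  rule <- match.arg(rule)
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  if (!all(dim(d1$values) == dim(d2$values)))
    stop("distance matrices differ in shape", call. = FALSE)
  if (!identical(d1$genuine_mask, d2$genuine_mask))
    stop("genuine masks differ", call. = FALSE)
  n1 <- minmax_normalize(d1)
  n2 <- minmax_normalize(d2)
  ws <- seq(0, 1, by = step)
  eers <- vapply(ws, function(w) {
    f <- d1
    f$values <- w * n1$values + (1 - w) * n2$values
    s <- verification_scores(f, rule)
    compute_eer(s$genuine, s$impostor)
  }, numeric(1))
  best <- which.min(eers)
  fused <- d1
  fused$metric <- paste0("fused(", d1$metric, ")")
  fused$values <- ws[best] * n1$values + (1 - ws[best]) * n2$values
  s <- verification_scores(fused, rule)
  structure(list(weight = ws[best], eer = eers[best],
                 eval = far_frr(s$genuine, s$impostor),
                 fused = fused,
                 grid = data.frame(w = ws, eer = eers)),
            class = "fusion_result")
}
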