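# end-to-end verification pipeline and the standard ablation battery
#
# full system: enhance -> WLPP channel (z-norm + LPP fitted on enrollment)
#                      -> LBPV_LPP channel (likewise)
#                      -> per-channel distance matrices -> weighted-sum fusion
#                      -> FAR/FRR/EER
# ablations: no-enhancement, no-LPP (raw concatenated vectors), WLPP-only,
# LBPV_LPP-only.

#' Pipeline configuration
#'
#' @param enhance a [matched_filter_params()].
#' @param wavelet a [wavelet_spec()].
#' @param lbp an [lbp_params()].
#' @param lpp an [lpp_config()]; applied per channel. If its `l` is `NULL`
#'   the pipeline uses the number of enrolled identities as the embedding
#'   dimension (capped by the enrollment size), since the between-identity
#'   structure spans about that many directions.
#' @param metrics distance metrics to evaluate.
#' @param fusion_step weight grid step for score fusion.
#' @param use_enhance apply matched-filter enhancement before features.
#' @param use_lpp project raw channel vectors with LPP.
#' @param channels feature channels to run (`"wlpp"`, `"lbpv_lpp"`).
#' @param score_rule genuine/impostor pairing rule, see
#'   [verification_scores()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(enhance = matched_filter_params(),
                            wavelet = wavelet_spec(),
                            lbp = lbp_params(),
                            lpp = lpp_config(),
                            metrics = c("euclidean", "manhattan", "cosine",
                                        "correlation"),
                            fusion_step = 0.01,
                            use_enhance = TRUE,
                            use_lpp = TRUE,
                            channels = c("wlpp", "lbpv_lpp"),
                            score_rule = "all_pairs") {
  channels <- match.arg(channels, several.ok = TRUE)
  structure(list(enhance = enhance, wavelet = wavelet, lbp = lbp, lpp = lpp,
                 metrics = metrics, fusion_step = fusion_step,
                 use_enhance = use_enhance, use_lpp = use_lpp,
                 channels = channels, score_rule = score_rule),
            class = "pipeline_config")
}

# channel feature matrices (all samples), LPP fitted on enrollment rows.
# When the LPP embedding dimension is left open, the pipeline uses the number
# of enrolled identities: the between-identity structure spans about that
# many directions, and smaller-eigenvalue coordinates beyond it are
# unit-normalized within-class noise that degrades the distance metric.
channel_features <- function(images, config, enroll, n_subjects) {
  out <- list()
  if ("wlpp" %in% config$channels) {
    wf <- wlpp_features(images, config$wavelet, enroll)
    out$wlpp <- wf$features
  }
  if ("lbpv_lpp" %in% config$channels) {
    lf <- lbpv_features(images, config$wavelet, config$lbp, enroll)
    out$lbpv_lpp <- lf$features
  }
  if (config$use_lpp) {
    lpp_cfg <- config$lpp
    if (is.null(lpp_cfg$l))
      lpp_cfg$l_max <- min(n_subjects, sum(enroll) - 1L)
    for (ch in names(out)) {
      model <- lpp_fit(out[[ch]][enroll, , drop = FALSE], lpp_cfg)
      out[[ch]] <- lpp_transform(model, out[[ch]])
    }
  }
  out
}

#' Run the verification pipeline on a labelled dataset
#'
#' @param dataset a `vein_dataset` (see [make_dataset()] / [read_dataset()]).
#' @param config a [pipeline_config()].
#' @param enhanced_images optional precomputed list of enhanced images
#'   (reused across ablation runs); ignored when `use_enhance` is `FALSE`.
#' @return Object of class `pipeline_report`: per-metric table of channel and
#'   fused EERs (percent) and fusion weights, rank-1 identification accuracy
#'   under the Euclidean metric, the full [far_frr()] result and ROC of the
#'   best fused metric, and the configuration echo.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         enhanced_images = NULL) {
  stopifnot(inherits(dataset, "vein_dataset"))
  t0 <- proc.time()[["elapsed"]]
  enroll <- dataset$meta$split == "enroll"
  imgs <- if (!config$use_enhance) dataset$images
          else if (!is.null(enhanced_images)) enhanced_images
          else lapply(dataset$images, enhance_image, params = config$enhance)

  feats <- channel_features(imgs, config, enroll,
                            length(unique(dataset$meta$subject_id)))
  subj <- dataset$meta$subject_id
  samp <- dataset$meta$sample_index
  two_ch <- length(feats) == 2

  rows <- list(); evals <- list(); id_acc <- list()
  for (metric in config$metrics) {
    dms <- lapply(feats, function(f)
      distance_matrix(f[!enroll, , drop = FALSE], f[enroll, , drop = FALSE],
                      metric,
                      test_subject = subj[!enroll],
                      enroll_subject = subj[enroll],
                      enroll_sample = samp[enroll]))
    ch_eer <- vapply(dms, function(d) {
      s <- verification_scores(d, config$score_rule)
      compute_eer(s$genuine, s$impostor)
    }, numeric(1))
    if (two_ch) {
      fus <- fuse_and_search(dms$wlpp, dms$lbpv_lpp, config$fusion_step,
                             config$score_rule)
      final_eer <- fus$eer; weight <- fus$weight
      evals[[metric]] <- fus$eval
      dm_final <- fus$fused
    } else {
      final_eer <- ch_eer[[1]]; weight <- NA_real_
      s <- verification_scores(dms[[1]], config$score_rule)
      evals[[metric]] <- far_frr(s$genuine, s$impostor)
      dm_final <- dms[[1]]
    }
    if (metric == "euclidean")
      id_acc <- lapply(c(dms, list(final = dm_final)), function(d)
        100 * mean(nn_identify(d) == subj[!enroll]))
    rows[[metric]] <- data.frame(
      metric = metric,
      eer_wlpp = if ("wlpp" %in% names(ch_eer)) ch_eer[["wlpp"]] else NA_real_,
      eer_lbpv_lpp = if ("lbpv_lpp" %in% names(ch_eer))
        ch_eer[["lbpv_lpp"]] else NA_real_,
      eer_final = final_eer, fusion_weight = weight,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  best_i <- which.min(table$eer_final)
  structure(list(
    table = table,
    best_metric = table$metric[best_i],
    eer = table$eer_final[best_i],
    id_accuracy = id_acc,
    eval_by_metric = evals,
    n_test = sum(!enroll), n_enroll = sum(enroll),
    config = config,
    elapsed_sec = proc.time()[["elapsed"]] - t0
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report —", x$n_test, "test vs", x$n_enroll, "enrolled samples\n")
  tbl <- x$table
  tbl[2:5] <- lapply(tbl[2:5], function(v) round(v, 4))
  print(tbl, row.names = FALSE)
  cat(sprintf("best: %s, EER = %.4f%%\n", x$best_metric, x$eer))
  invisible(x)
}

#' Run the full experiment battery (system + ablations)
#'
#' Experiments mirror the standard ablation layout: the full system, the
#' system without image enhancement, without LPP, and each feature channel
#' alone. Enhanced images are computed once and shared.
#'
#' @param dataset a `vein_dataset`.
#' @param config a [pipeline_config()] for the full system.
#' @param ablations run the four ablations in addition to the full system.
#' @return Object of class `experiment_report`: named list of
#'   `pipeline_report`s (`full`, and with ablations `no_enhance`, `no_lpp`,
#'   `wlpp_only`, `lbpv_lpp_only`) plus a combined summary data.frame.
#' @export
run_experiments <- function(dataset, config = pipeline_config(),
                            ablations = TRUE) {
  enhanced <- if (config$use_enhance)
    lapply(dataset$images, enhance_image, params = config$enhance) else NULL
  runs <- list(full = run_pipeline(dataset, config, enhanced))
  if (ablations) {
    vary <- list(
      no_enhance = modifyList(config, list(use_enhance = FALSE)),
      no_lpp = modifyList(config, list(use_lpp = FALSE)),
      wlpp_only = modifyList(config, list(channels = "wlpp")),
      lbpv_lpp_only = modifyList(config, list(channels = "lbpv_lpp")))
    for (nm in names(vary)) {
      cfg <- structure(vary[[nm]], class = "pipeline_config")
      runs[[nm]] <- run_pipeline(dataset, cfg,
                                 if (cfg$use_enhance) enhanced else NULL)
    }
  }
  summary <- do.call(rbind, lapply(names(runs), function(nm)
    cbind(experiment = nm, runs[[nm]]$table,
          stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  tbl <- x$summary
  tbl[3:6] <- lapply(tbl[3:6], function(v) round(v, 4))
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Write a machine-readable experiment report
#'
#' JSON summary (EER tables, fusion weights, identification accuracy) plus
#' CSV tables of the per-metric EERs and of the best fused FAR/FRR/ROC
#' points.
#'
#' @param report an [run_experiments()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "eer_tables.csv"),
                   row.names = FALSE)
  full <- report$runs$full
  ev <- full$eval_by_metric[[full$best_metric]]
  utils::write.csv(
    data.frame(threshold = ev$thresholds, far = ev$far, frr = ev$frr),
    file.path(dir, "far_frr_best.csv"), row.names = FALSE)
  utils::write.csv(ev$roc, file.path(dir, "roc_best.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    summary = report$summary,
    best = list(metric = full$best_metric, eer_pct = full$eer,
                id_accuracy_pct = full$id_accuracy),
    elapsed_sec = vapply(report$runs, `[[`, numeric(1), "elapsed_sec")
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
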