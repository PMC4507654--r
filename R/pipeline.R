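#' Run the envelope pipeline on one recording
#'
#' Detrends the cuff pressure into the oscillometric waveform, segments it
#' into per-beat pulses, optionally removes artifact pulses, fits the
#' envelope spline and extracts the ten features. When the recording carries
#' reference pressures inside the envelope domain, the reference
#' characteristic ratios are computed as well.
#'
#' @param rec a `cuff_recording`.
#' @param artifact_removal apply the outlier screen before envelope fitting.
#' @param outlier_cfg an [outlier_config()].
#' @param amplitude knot amplitude mode, see [build_owe()].
#' @return list with `pulses` (all segmented pulses), `clean_pulses`,
#'   `flags`, `rise_intervals`, `owe` (fitted), `features` and `ratios`
#'   (reference `ratio_pair` or `NULL`).
#' @export
process_recording <- function(rec, artifact_removal = TRUE,
                              outlier_cfg = outlier_config(),
                              amplitude = "pk2bt") {
  omw <- detrend_oscillometric(rec$cp, rec$fs)
  baseline <- lowpass_cuff_baseline(rec$cp, rec$fs)
  pulses <- segment_pulses(omw, rec, baseline)
  flags <- NULL
  rises <- NULL
  clean <- pulses
  if (artifact_removal) {
    flags <- flag_outlier_pulses(pulses, outlier_cfg)
    rises <- flag_pressure_rises(baseline, rec$fs, outlier_cfg)
    clean <- remove_outliers(pulses, flags, rises)
  }
  owe <- suppressWarnings(fit_spline(build_owe(clean, amplitude = amplitude)))
  feats <- extract_features(owe)
  ratios <- NULL
  if (is.finite(rec$reference_sbp) && is.finite(rec$reference_dbp)) {
    ratios <- tryCatch(reference_ratios(owe, rec$reference_sbp,
                                        rec$reference_dbp),
                       error = function(e) NULL)
  }
  list(pulses = pulses, clean_pulses = clean, flags = flags,
       rise_intervals = rises, owe = owe, features = feats, ratios = ratios)
}

#' Process a list of recordings into a cohort
#'
#' Runs [process_recording()] on each recording and assembles the aligned
#' `bp_cohort`. Recordings that fail (too few clean pulses, reference
#' pressures outside the envelope domain, ...) are dropped; their ids and
#' error messages are attached as attribute `failures`.
#'
#' @param recordings list of `cuff_recording`s, or of `list(recording, ...)`
#'   pairs as returned by [generate_cohort()].
#' @inheritParams process_recording
#' @return a [bp_cohort()] (with attribute `failures`).
#' @export
process_cohort <- function(recordings, artifact_removal = TRUE,
                           outlier_cfg = outlier_config(),
                           amplitude = "pk2bt") {
  recs <- lapply(recordings, function(r)
    if (inherits(r, "cuff_recording")) r else r$recording)
  rows <- list()
  failures <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    pr <- tryCatch(process_recording(rec, artifact_removal, outlier_cfg,
                                     amplitude),
                   error = function(e) e)
    id <- if (is.null(rec$meta$id)) i else rec$meta$id
    if (inherits(pr, "error") || is.null(pr$ratios)) {
      msg <- if (inherits(pr, "error")) conditionMessage(pr)
             else "reference ratios unavailable"
      failures[[length(failures) + 1L]] <- data.frame(id = id, error = msg)
      next
    }
    rows[[length(rows) + 1L]] <-
      list(features = pr$features, owe = pr$owe,
           ref_sbp = rec$reference_sbp, ref_dbp = rec$reference_dbp,
           sbpr = pr$ratios$sbpr, dbpr = pr$ratios$dbpr,
           subject = if (is.null(rec$meta$subject)) i else rec$meta$subject,
           id = id)
  }
  if (length(rows) < 2L)
    stop("fewer than 2 recordings survived processing")
  cohort <- bp_cohort(
    features = as.data.frame(do.call(rbind, lapply(rows, `[[`, "features"))),
    owe = lapply(rows, `[[`, "owe"),
    ref_sbp = vapply(rows, `[[`, numeric(1), "ref_sbp"),
    ref_dbp = vapply(rows, `[[`, numeric(1), "ref_dbp"),
    sbpr = vapply(rows, `[[`, numeric(1), "sbpr"),
    dbpr = vapply(rows, `[[`, numeric(1), "dbpr"),
    subject = vapply(rows, `[[`, numeric(1), "subject"),
    id = vapply(rows, function(r) as.character(r$id), character(1)))
  attr(cohort, "failures") <- if (length(failures))
    do.call(rbind, failures) else NULL
  cohort
}

#' Cross-validated blood-pressure estimation and grading on a cohort
#'
#' Fits the chosen ratio estimator under the cross-validation plan (each
#' recording's ratios predicted by models trained on the other folds),
#' inverts the predicted ratios on each recording's envelope, and grades the
#' estimates against the reference pressures. With `features = "auto"` the
#' feature set is chosen by [exhaustive_search()] followed by [sffs()].
#'
#' @param cohort a `bp_cohort`.
#' @param estimator `"maa"`, `"mlr"` or `"nusvr"`.
#' @param features character vector of feature names, or `"auto"`.
#' @param plan a [kfold_split()] plan; default 4-fold by subject.
#' @param out_dir optional directory; when given, the estimates CSV and the
#'   report JSON are written there.
#' @return list with `report_sbp`, `report_dbp` (class `bp_eval_report`),
#'   `estimates` (data frame), `features`, `selection` (when `auto`).
#' @export
run_pipeline <- function(cohort, estimator = c("mlr", "maa", "nusvr"),
                         features = c("ratio2", "area3"), plan = NULL,
                         out_dir = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(cohort, "bp_cohort"))
  if (is.null(plan)) plan <- kfold_split(cohort, k = 4L)
  selection <- NULL
  if (identical(features, "auto") && estimator != "maa") {
    ex <- exhaustive_search(cohort, estimator, plan)
    selection <- sffs(cohort, estimator, plan, ex$best_set)
    selection$exhaustive <- ex
    features <- selection$best_set
  }
  res_s <- cv_differences(cohort, features, estimator, plan, "sbp")
  res_d <- cv_differences(cohort, features, estimator, plan, "dbp")
  est <- data.frame(recording_id = cohort$id,
                    subject = cohort$subject,
                    fold = plan$assignments,
                    sbp_est = res_s$est, dbp_est = res_d$est,
                    map_est = vapply(cohort$owe, function(o) o$map,
                                     numeric(1)),
                    sbp_ref = cohort$ref_sbp, dbp_ref = cohort$ref_dbp,
                    sbpr_pred = res_s$pred_ratio,
                    dbpr_pred = res_d$pred_ratio)
  out <- list(report_sbp = eval_report(res_s$est, cohort$ref_sbp),
              report_dbp = eval_report(res_d$est, cohort$ref_dbp),
              estimates = est, estimator = estimator,
              features = features, plan = plan, selection = selection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    rep <- list(estimator = estimator, features = features,
                k = plan$k, grouping = plan$grouping,
                report_sbp = unclass(out$report_sbp),
                report_dbp = unclass(out$report_dbp))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
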