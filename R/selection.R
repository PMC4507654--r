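#' Processed cohort container
#'
#' Aligned per-recording results of the envelope pipeline, as consumed by
#' model fitting, feature selection and the pipeline driver: the feature
#' matrix, the fitted envelopes, reference pressures and reference
#' characteristic ratios, and grouping identifiers.
#'
#' @param features data frame of envelope features (columns from
#'   [bp_feature_names]), one row per recording.
#' @param owe list of fitted `owe` objects.
#' @param ref_sbp,ref_dbp reference pressures, mmHg.
#' @param sbpr,dbpr reference characteristic ratios.
#' @param subject grouping identifier (integer or character) per recording.
#' @param id recording identifiers.
#' @return object of class `bp_cohort`.
#' @export
bp_cohort <- function(features, owe, ref_sbp, ref_dbp, sbpr, dbpr,
                      subject = seq_len(nrow(features)),
                      id = seq_len(nrow(features))) {
  n <- nrow(features)
  stopifnot(length(owe) == n, length(ref_sbp) == n, length(ref_dbp) == n,
            length(sbpr) == n, length(dbpr) == n, length(subject) == n)
  structure(list(features = features, owe = owe, ref_sbp = ref_sbp,
                 ref_dbp = ref_dbp, sbpr = sbpr, dbpr = dbpr,
                 subject = subject, id = id, n = n),
            class = "bp_cohort")
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("<bp_cohort: %d recordings, %d subjects, %d features>\n",
              x$n, length(unique(x$subject)), ncol(x$features)))
  invisible(x)
}

#' Grouped k-fold cross-validation plan
#'
#' Groups (subjects, or single recordings) are shuffled deterministically
#' under `seed` and dealt round-robin into `k` folds, so fold sizes are
#' balanced within one group. With `by_subject` grouping, all recordings of
#' a subject share a fold, preventing within-subject leakage.
#'
#' @param cohort a `bp_cohort`.
#' @param k number of folds.
#' @param grouping `"by_subject"` or `"by_recording"`.
#' @param seed integer seed for the shuffle.
#' @return object of class `cv_plan` with the per-recording fold
#'   `assignments`.
#' @export
kfold_split <- function(cohort, k = 4L, grouping = c("by_subject",
                                                     "by_recording"),
                        seed = 1L) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "by_subject") cohort$subject
            else seq_len(cohort$n)
  ug <- unique(groups)
  if (length(ug) < k)
    stop("fewer groups (", length(ug), ") than folds (", k, ")")
  set.seed(as.integer(seed))
  ug <- sample(ug)
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                                   ug)
  structure(list(k = as.integer(k), grouping = grouping,
                 seed = as.integer(seed),
                 assignments = unname(fold_of_group[as.character(groups)])),
            class = "cv_plan")
}

ratio_pair <- function(sbpr, dbpr = NA_real_)
  structure(list(sbpr = sbpr, dbpr = dbpr), class = "ratio_pair")

## Train on the training rows and predict a single ratio target on all rows.
fit_predict_ratio <- function(cohort, feats, estimator_kind, train_idx,
                              target_ratio) {
  y <- cohort[[target_ratio]]
  if (estimator_kind == "maa")
    return(rep(mean(y[train_idx]), cohort$n))
  X <- as.matrix(cohort$features[, feats, drop = FALSE])
  model <- switch(estimator_kind,
                  mlr = fit_mlr(cbind(`(Intercept)` = 1,
                                      X[train_idx, , drop = FALSE]),
                                y[train_idx]),
                  nusvr = fit_nusvr(X[train_idx, , drop = FALSE],
                                    y[train_idx]),
                  stop("unknown estimator kind: ", estimator_kind))
  suppressMessages(clip_ratios(predict_linear(model, X)))
}

## Cross-validated pressure differences (reference - estimate) for one
## feature subset and estimator; target is "sbp" or "dbp".
cv_differences <- function(cohort, feats, estimator_kind, plan,
                           target = "sbp") {
  ratio_name <- if (target == "sbp") "sbpr" else "dbpr"
  ref <- cohort[[if (target == "sbp") "ref_sbp" else "ref_dbp"]]
  est <- rep(NA_real_, cohort$n)
  pred <- rep(NA_real_, cohort$n)
  for (f in seq_len(plan$k)) {
    test <- which(plan$assignments == f)
    train <- which(plan$assignments != f)
    if (!length(test)) next
    p <- fit_predict_ratio(cohort, feats, estimator_kind, train, ratio_name)
    pred[test] <- p[test]
    for (i in test) {
      r <- if (target == "sbp") ratio_pair(sbpr = p[i])
           else ratio_pair(sbpr = 1, dbpr = p[i])
      bp <- estimate_bp_from_ratios(cohort$owe[[i]], r)
      est[i] <- if (target == "sbp") bp$sbp else bp$dbp
    }
  }
  list(diff = ref - est, est = est, pred_ratio = pred)
}

score_candidate <- function(cohort, feats, estimator_kind, plan, target,
                            criterion) {
  res <- tryCatch(cv_differences(cohort, feats, estimator_kind, plan,
                                 target),
                  error = function(e) e)
  if (inherits(res, "error"))
    return(structure(NA_real_, reason = conditionMessage(res)))
  d <- res$diff[is.finite(res$diff)]
  if (length(d) < 2L) return(structure(NA_real_, reason = "too few estimates"))
  switch(criterion, sd = stats::sd(d), mae = mean(abs(d)),
         stop("unknown criterion: ", criterion))
}

#' Exhaustive search over single features and feature pairs
#'
#' Enumerates all subsets of size 1 or 2 of the ten envelope features
#' (10 + 45 = 55 candidates) and scores each by the cross-validated
#' criterion on the pressure differences (default: SD of reference minus
#' estimated SBP). Candidates are ranked ascending; ties are broken by
#' fewer features, then lexicographic feature names. Candidates whose
#' estimator fails on any fold are excluded from the ranking and reported
#' in `failed`.
#'
#' @param cohort a `bp_cohort`.
#' @param estimator_kind `"mlr"`, `"nusvr"` or `"maa"` (for `"maa"` the
#'   features are ignored by the estimator but still enumerated).
#' @param plan a [kfold_split()] plan.
#' @param criterion `"sd"` (SD of differences) or `"mae"`.
#' @param target `"sbp"` or `"dbp"`.
#' @param feature_names candidate pool (default [bp_feature_names]).
#' @return object of class `selection_result` with `candidates` (ranked data
#'   frame), `best_set`, `failed` and the scoring context.
#' @export
exhaustive_search <- function(cohort, estimator_kind = "mlr", plan,
                              criterion = "sd", target = "sbp",
                              feature_names = bp_feature_names) {
  stopifnot(inherits(cohort, "bp_cohort"), inherits(plan, "cv_plan"))
  sets <- c(lapply(feature_names, identity),
            utils::combn(feature_names, 2L, simplify = FALSE))
  scores <- vapply(sets, function(s)
    as.numeric(score_candidate(cohort, s, estimator_kind, plan, target,
                               criterion)), numeric(1))
  labels <- vapply(sets, paste, character(1), collapse = "+")
  cand <- data.frame(features = labels,
                     n_features = lengths(sets),
                     score = scores, stringsAsFactors = FALSE)
  ok <- is.finite(cand$score)
  ranked <- cand[ok, , drop = FALSE]
  ranked <- ranked[order(ranked$score, ranked$n_features, ranked$features), ,
                   drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  if (!nrow(ranked)) stop("every candidate failed during cross-validation")
  structure(list(candidates = ranked,
                 best_set = strsplit(ranked$features[1L], "+",
                                     fixed = TRUE)[[1L]],
                 failed = cand[!ok, , drop = FALSE],
                 estimator_kind = estimator_kind, criterion = criterion,
                 target = target, trajectory = NULL),
            class = "selection_result")
}

#' Sequential forward floating selection (SFFS)
#'
#' Starting from `start_set` (normally the best pair from
#' [exhaustive_search()]), repeatedly adds the feature whose inclusion most
#' improves the cross-validated criterion, then conditionally removes
#' features (other than the one just added) while removal improves it.
#' Stops when no addition improves the criterion by more than `tol`
#' (relative). The default `tol = 0.1` demands a 10% improvement of the
#' cross-validated criterion before growing the set: the CV estimate of an
#' error SD has a relative sampling error of roughly `1/sqrt(2n)` at cohort
#' size `n`, so smaller apparent gains are indistinguishable from chance and
#' accepting them lets uninformative features accumulate.
#'
#' @inheritParams exhaustive_search
#' @param start_set character vector of starting features.
#' @param tol relative improvement threshold for accepting a step.
#' @param min_size smallest set the backward step may reach.
#' @return a `selection_result` with the `trajectory` of accepted and
#'   rejected steps.
#' @export
sffs <- function(cohort, estimator_kind = "mlr", plan, start_set,
                 criterion = "sd", target = "sbp",
                 feature_names = bp_feature_names, tol = 0.1,
                 min_size = 1L) {
  stopifnot(all(start_set %in% feature_names), length(start_set) >= 1L)
  memo <- new.env(parent = emptyenv())
  score <- function(s) {
    key <- paste(sort(s), collapse = "+")
    if (exists(key, envir = memo, inherits = FALSE))
      return(get(key, envir = memo, inherits = FALSE))
    v <- as.numeric(score_candidate(cohort, s, estimator_kind, plan, target,
                                    criterion))
    assign(key, v, envir = memo)
    v
  }
  improves <- function(new, old) is.finite(new) && new < old - tol * abs(old)

  cur <- start_set
  cur_score <- score(cur)
  if (!is.finite(cur_score)) stop("starting set failed cross-validation")
  traj <- list(list(action = "start", feature = NA_character_,
                    set = cur, score = cur_score))
  repeat {
    pool <- setdiff(feature_names, cur)
    if (!length(pool)) break
    add_scores <- vapply(pool, function(f) score(c(cur, f)), numeric(1))
    j <- which.min(add_scores)
    if (!improves(add_scores[j], cur_score)) {
      traj[[length(traj) + 1L]] <- list(action = "reject-add",
                                        feature = pool[j],
                                        set = cur, score = cur_score)
      break
    }
    added <- pool[j]
    cur <- c(cur, added)
    cur_score <- add_scores[j]
    traj[[length(traj) + 1L]] <- list(action = "add", feature = added,
                                      set = cur, score = cur_score)
    repeat {   # floating backward step
      if (length(cur) <= min_size) break
      removable <- setdiff(cur, added)
      if (!length(removable)) break
      rem_scores <- vapply(removable, function(f)
        score(setdiff(cur, f)), numeric(1))
      r <- which.min(rem_scores)
      if (!improves(rem_scores[r], cur_score)) break
      cur <- setdiff(cur, removable[r])
      cur_score <- rem_scores[r]
      traj[[length(traj) + 1L]] <- list(action = "remove",
                                        feature = removable[r],
                                        set = cur, score = cur_score)
    }
  }
  structure(list(candidates = data.frame(
                   features = paste(sort(cur), collapse = "+"),
                   n_features = length(cur), score = cur_score, rank = 1L),
                 best_set = cur, best_score = cur_score,
                 failed = NULL, estimator_kind = estimator_kind,
                 criterion = criterion, target = target, trajectory = traj),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result (%s, %s of %s differences): best set {%s}",
              x$estimator_kind, x$criterion, toupper(x$target),
              paste(x$best_set, collapse = ", ")))
  cat(sprintf(", score %.3f mmHg>\n", x$candidates$score[1L]))
  invisible(x)
}
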