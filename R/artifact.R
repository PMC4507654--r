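#' Configuration of the outlier-pulse screen
#'
#' Thresholds of the movement-artifact rules applied before envelope fitting.
#' A pulse is screened on four height series (peak, bottom and the two
#' peak-to-trough heights): it must not deviate from the median of its
#' neighbouring pulses by a relative variation above `max_abs_variation`,
#' and each height must lie within `±neighbour_tolerance` (fraction) of that
#' neighbour median. Independently, intervals where the low-passed cuff
#' pressure rises faster than `rise_slope_threshold` for at least
#' `rise_min_duration` during deflation are treated as artifact.
#'
#' @param max_abs_variation maximum relative deviation from the neighbour
#'   median (dimensionless).
#' @param neighbour_tolerance allowed fractional band around the neighbour
#'   median.
#' @param neighbour_halfwidth number of neighbour pulses on each side.
#' @param rise_slope_threshold baseline slope above which a pressure rise is
#'   flagged, mmHg/s.
#' @param rise_min_duration minimum duration of a flagged rise, s.
#' @param eps small mmHg constant guarding division by a near-zero median.
#' @param edge_guard_s leading/trailing seconds excluded from the
#'   pressure-rise scan (filter edge region and inflation remnants).
#' @return object of class `outlier_config`.
#' @export
outlier_config <- function(max_abs_variation = 0.4,
                           neighbour_tolerance = 0.5,
                           neighbour_halfwidth = 2L,
                           rise_slope_threshold = 1.0,
                           rise_min_duration = 0.2,
                           eps = 1e-6,
                           edge_guard_s = 2) {
  stopifnot(max_abs_variation > 0, neighbour_tolerance > 0,
            neighbour_halfwidth >= 1L, rise_slope_threshold > 0,
            rise_min_duration > 0, eps > 0)
  structure(list(max_abs_variation = max_abs_variation,
                 neighbour_tolerance = neighbour_tolerance,
                 neighbour_halfwidth = as.integer(neighbour_halfwidth),
                 rise_slope_threshold = rise_slope_threshold,
                 rise_min_duration = rise_min_duration,
                 eps = eps, edge_guard_s = edge_guard_s),
            class = "outlier_config")
}

#' Flag outlier pulses by comparison with neighbouring pulses
#'
#' Each of the four per-pulse height series is compared with the median of
#' the `neighbour_halfwidth` pulses on each side (the pulse itself excluded;
#' windows are clipped at the recording ends). A pulse is flagged when, on
#' any series, its relative deviation from the neighbour median exceeds
#' `max_abs_variation` ("abs-variation") or its height falls outside the
#' `±neighbour_tolerance` band around that median ("neighbour-band").
#' The first and last pulse have no neighbour on one side, so no symmetric
#' context exists to judge them against the steeply trending envelope; they
#' are exempt from the neighbour screen (the pressure-rise rule still
#' applies to them).
#'
#' @param pulses a `bp_pulses` data frame from [segment_pulses()].
#' @param cfg an [outlier_config()].
#' @return data frame with columns `index`, `series`, `reason` (one row per
#'   rule firing; a pulse may appear several times).
#' @export
flag_outlier_pulses <- function(pulses, cfg = outlier_config()) {
  hw <- cfg$neighbour_halfwidth
  n <- nrow(pulses)
  if (n < 2L * hw + 1L)
    stop("need at least ", 2L * hw + 1L, " pulses for the neighbour screen")
  series <- c("peak_value", "bottom_value", "pk2bt_prev", "pk2bt_next")
  hits <- list()
  for (s in series) {
    h <- pulses[[s]]
    for (i in 2L:(n - 1L)) {
      nb <- setdiff(max(1L, i - hw):min(n, i + hw), i)
      m <- stats::median(h[nb])
      rel <- abs(h[i] - m) / max(abs(m), cfg$eps)
      lo <- min((1 - cfg$neighbour_tolerance) * m,
                (1 + cfg$neighbour_tolerance) * m)
      hi <- max((1 - cfg$neighbour_tolerance) * m,
                (1 + cfg$neighbour_tolerance) * m)
      if (rel > cfg$max_abs_variation)
        hits[[length(hits) + 1L]] <- data.frame(index = i, series = s,
                                                reason = "abs-variation")
      else if (h[i] < lo || h[i] > hi)
        hits[[length(hits) + 1L]] <- data.frame(index = i, series = s,
                                                reason = "neighbour-band")
    }
  }
  if (!length(hits))
    return(data.frame(index = integer(), series = character(),
                      reason = character()))
  do.call(rbind, hits)
}

#' Detect sudden pressure rises during cuff deflation
#'
#' Returns maximal time intervals in which the slope of the low-passed cuff
#' pressure exceeds `rise_slope_threshold` for at least `rise_min_duration`.
#' During a valve-controlled deflation the baseline slope is negative, so a
#' sustained positive slope indicates arm movement or cuff disturbance.
#' The first and last `edge_guard_s` seconds are excluded (filter edge
#' region / inflation remnants).
#'
#' @param baseline low-passed cuff pressure from [lowpass_cuff_baseline()].
#' @param fs sampling rate, Hz.
#' @param cfg an [outlier_config()].
#' @return data frame with columns `t0`, `t1` (s), in time order (zero rows
#'   when no rise is found).
#' @export
flag_pressure_rises <- function(baseline, fs, cfg = outlier_config()) {
  n <- length(baseline)
  slope <- c(diff(baseline) * fs, NA_real_)
  guard <- ceiling(cfg$edge_guard_s * fs)
  ok <- !is.na(slope) & slope > cfg$rise_slope_threshold
  if (guard > 0L) {
    ok[seq_len(min(guard, n))] <- FALSE
    ok[max(1L, n - guard):n] <- FALSE
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$rise_min_duration * fs
  if (!any(keep)) return(data.frame(t0 = numeric(), t1 = numeric()))
  data.frame(t0 = (starts[keep] - 1) / fs, t1 = (ends[keep] - 1) / fs)
}

#' Remove flagged outlier pulses before envelope fitting
#'
#' Drops every pulse flagged by [flag_outlier_pulses()] and every pulse whose
#' peak time falls inside a pressure-rise interval from
#' [flag_pressure_rises()]. The input is not modified; pulse order is
#' preserved.
#'
#' @param pulses a `bp_pulses` data frame.
#' @param flags flag report from [flag_outlier_pulses()].
#' @param rise_intervals interval table from [flag_pressure_rises()].
#' @return the surviving pulses (`bp_pulses`); an error is raised when fewer
#'   than 4 pulses survive, since the envelope spline needs at least 4 knots.
#' @export
remove_outliers <- function(pulses, flags = NULL, rise_intervals = NULL) {
  drop <- rep(FALSE, nrow(pulses))
  if (!is.null(flags) && nrow(flags)) drop[unique(flags$index)] <- TRUE
  if (!is.null(rise_intervals) && nrow(rise_intervals)) {
    for (j in seq_len(nrow(rise_intervals)))
      drop <- drop | (pulses$t_peak >= rise_intervals$t0[j] &
                        pulses$t_peak <= rise_intervals$t1[j])
  }
  out <- pulses[!drop, , drop = FALSE]
  if (nrow(out) < 4L)
    stop("fewer than 4 pulses survive outlier removal; ",
         "cannot fit an envelope spline")
  rownames(out) <- NULL
  class(out) <- c("bp_pulses", "data.frame")
  out
}
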