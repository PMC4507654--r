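#' Build the oscillometric waveform envelope knot set
#'
#' One knot per clean pulse at `(cp_at_peak, amplitude, t_peak)`. The knot
#' amplitude is by default the mean of the two peak-to-trough heights, which
#' measures oscillation magnitude robustly against residual baseline in the
#' detrended waveform; `amplitude = "peak"` uses the raw peak value instead.
#' Knots sharing (near-identical) cuff pressure are merged by averaging
#' amplitude and time.
#'
#' @param clean_pulses a `bp_pulses` data frame, normally after
#'   [remove_outliers()].
#' @param amplitude `"pk2bt"` (mean peak-to-trough, default) or `"peak"`.
#' @param merge_tol knots closer than this in cuff pressure (mmHg) are
#'   merged.
#' @return object of class `owe` holding `knots` (sorted by ascending cuff
#'   pressure) and `knots_time` (sorted by time, used for duration/area
#'   features); the spline is added by [fit_spline()].
#' @export
build_owe <- function(clean_pulses, amplitude = c("pk2bt", "peak"),
                      merge_tol = 0.05) {
  amplitude <- match.arg(amplitude)
  if (nrow(clean_pulses) < 4L) stop("need at least 4 clean pulses")
  amp <- switch(amplitude,
                pk2bt = (clean_pulses$pk2bt_prev + clean_pulses$pk2bt_next) / 2,
                peak = clean_pulses$peak_value)
  k <- data.frame(cp = clean_pulses$cp_at_peak, amplitude = amp,
                  t = clean_pulses$t_peak)
  k <- k[order(k$cp), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(k$cp) > merge_tol))
  merged <- data.frame(
    cp = as.numeric(tapply(k$cp, grp, mean)),
    amplitude = as.numeric(tapply(k$amplitude, grp, mean)),
    t = as.numeric(tapply(k$t, grp, mean)))
  rownames(merged) <- NULL
  if (nrow(merged) < 4L)
    stop("fewer than 4 distinct cuff-pressure knots after merging")
  structure(list(knots = merged,
                 knots_time = merged[order(merged$t), , drop = FALSE],
                 spline = NULL, ma = NA_real_, map = NA_real_,
                 map_at_boundary = FALSE),
            class = "owe")
}

#' Fit a natural interpolating cubic spline through the envelope knots
#'
#' The spline interpolates amplitude as a function of cuff pressure with
#' natural boundary conditions; the maximum amplitude (MA) and its cuff
#' pressure (MAP) are located by [locate_map()] on the fitted curve.
#'
#' @param owe an `owe` from [build_owe()], or a data frame of knots with
#'   columns `cp`, `amplitude` and optionally `t`.
#' @return the `owe` with `spline` (a function of cuff pressure), `ma`,
#'   `map` and `map_at_boundary` filled in.
#' @export
fit_spline <- function(owe) {
  if (is.data.frame(owe)) {
    k <- owe
    if (is.null(k$t)) k$t <- seq_len(nrow(k))
    owe <- structure(list(knots = k[order(k$cp), , drop = FALSE],
                          knots_time = k[order(k$t), , drop = FALSE],
                          spline = NULL, ma = NA_real_, map = NA_real_,
                          map_at_boundary = FALSE),
                     class = "owe")
  }
  k <- owe$knots
  if (nrow(k) < 4L) stop("need at least 4 knots")
  if (any(diff(k$cp) <= 0))
    stop("coincident cuff-pressure knots; merge before fitting")
  owe$spline <- stats::splinefun(k$cp, k$amplitude, method = "natural")
  loc <- locate_map(owe)
  owe$ma <- loc$ma
  owe$map <- loc$map
  owe$map_at_boundary <- loc$at_boundary
  owe
}

#' Evaluate the fitted envelope at given cuff pressures
#'
#' @param owe a fitted `owe`.
#' @param cp cuff pressure(s), mmHg; must lie inside the knot domain.
#' @return amplitude(s), mmHg.
#' @export
owe_eval <- function(owe, cp) {
  if (is.null(owe$spline)) stop("envelope spline not fitted; see fit_spline()")
  dom <- range(owe$knots$cp)
  if (any(cp < dom[1] - 1e-9 | cp > dom[2] + 1e-9))
    stop(sprintf("cuff pressure outside the envelope domain [%.2f, %.2f]",
                 dom[1], dom[2]))
  owe$spline(pmin(pmax(cp, dom[1]), dom[2]))
}

#' Locate the envelope maximum (MA) and its cuff pressure (MAP)
#'
#' Scans the spline on a 0.1 mmHg grid and refines the best bracket by
#' golden-section/parabolic maximization to 0.01 mmHg. When two grid maxima
#' tie (within 1e-9 relative), the one at higher cuff pressure is returned.
#' A maximum at a domain endpoint sets the `at_boundary` flag (truncated
#' envelope).
#'
#' @param owe a fitted `owe` (or one whose spline was just built).
#' @return list with `map` (mmHg), `ma` (mmHg) and `at_boundary` (logical).
#' @export
locate_map <- function(owe) {
  if (is.null(owe$spline)) stop("envelope spline not fitted")
  dom <- range(owe$knots$cp)
  grid <- unique(c(seq(dom[1], dom[2], by = 0.1), dom[2]))
  v <- owe$spline(grid)
  vmax <- max(v)
  ties <- which(v >= vmax - 1e-9 * max(abs(vmax), 1))
  i <- ties[length(ties)]            # tie-break: highest cuff pressure
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(owe$spline, c(lo, hi), maximum = TRUE,
                           tol = 1e-4)
    map <- opt$maximum
    ma <- opt$objective
    if (v[i] > ma) { map <- grid[i]; ma <- v[i] }
  } else {
    map <- grid[i]
    ma <- v[i]
  }
  at_boundary <- (map - dom[1] < 0.15) || (dom[2] - map < 0.15)
  if (at_boundary)
    warning("envelope maximum lies at the domain boundary; envelope truncated")
  list(map = map, ma = ma, at_boundary = at_boundary)
}

#' @export
print.owe <- function(x, ...) {
  cat(sprintf("<owe: %d knots on [%.1f, %.1f] mmHg", nrow(x$knots),
              min(x$knots$cp), max(x$knots$cp)))
  if (is.finite(x$ma))
    cat(sprintf(", MA = %.3f mmHg at MAP = %.2f mmHg", x$ma, x$map))
  cat(">\n")
  invisible(x)
}
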