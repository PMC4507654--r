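#' Names of the ten envelope features
#'
#' Amplitude (`amp1` = MA), durations (`dur1` = time from envelope onset to
#' the MA position, `dur2` = envelope duration), areas under the envelope
#' over time (`area1` total, `area2` before the MA position, `area3` after),
#' shape ratios (`ratio1` = dur1/dur2, `ratio2` = area2/area1, `ratio3` =
#' area3/area1) and `map_maa`, the MAP estimate of the maximum amplitude
#' algorithm.
#' @export
bp_feature_names <- c("amp1", "dur1", "dur2", "area1", "area2", "area3",
                      "ratio1", "ratio2", "ratio3", "map_maa")

## time at the refined MAP pressure, linearly interpolated between the
## cp-sorted knots bracketing it
owe_time_at_map <- function(owe) {
  k <- owe$knots
  i <- findInterval(owe$map, k$cp, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(k) - 1L)
  w <- (owe$map - k$cp[i]) / (k$cp[i + 1L] - k$cp[i])
  k$t[i] + w * (k$t[i + 1L] - k$t[i])
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Extract the ten envelope features
#'
#' Durations and areas are computed on the time axis using the per-knot peak
#' times (the deflation is near-linear, so the pressure axis would be
#' proportional); areas are trapezoidal integrals of the piecewise-linear
#' knot envelope, split at the MA position. The MA time is obtained by
#' interpolating knot time at the refined MAP pressure.
#'
#' @param owe a fitted `owe` (see [fit_spline()]).
#' @return named numeric vector with entries [bp_feature_names]: mmHg for
#'   `amp1` and `map_maa`, seconds for durations, mmHg*s for areas,
#'   dimensionless ratios.
#' @export
extract_features <- function(owe) {
  if (is.null(owe$spline) || !is.finite(owe$ma))
    stop("envelope must be fitted before feature extraction")
  kt <- owe$knots_time
  t0 <- kt$t[1L]
  t1 <- kt$t[nrow(kt)]
  dur2 <- t1 - t0
  if (dur2 <= 0) stop("degenerate envelope: zero duration")
  t_map <- owe_time_at_map(owe)

  tt <- kt$t
  aa <- kt$amplitude
  if (t_map > t0 && t_map < t1 && !any(abs(tt - t_map) < 1e-12)) {
    a_map <- stats::approx(tt, aa, xout = t_map)$y
    ins <- findInterval(t_map, tt)
    tt <- append(tt, t_map, after = ins)
    aa <- append(aa, a_map, after = ins)
  }
  pre <- tt <= t_map + 1e-12
  area1 <- trapz(tt, aa)
  area2 <- if (sum(pre) >= 2L) trapz(tt[pre], aa[pre]) else 0
  area3 <- area1 - area2

  c(amp1 = owe$ma,
    dur1 = t_map - t0,
    dur2 = dur2,
    area1 = area1, area2 = area2, area3 = area3,
    ratio1 = (t_map - t0) / dur2,
    ratio2 = if (area1 > 0) area2 / area1 else NA_real_,
    ratio3 = if (area1 > 0) area3 / area1 else NA_real_,
    map_maa = owe$map)
}

#' Reference characteristic ratios from reference pressures
#'
#' The systolic and diastolic characteristic ratios are the envelope
#' amplitudes at the reference SBP and DBP divided by the maximum amplitude:
#' `sbpr = A(SBP)/MA`, `dbpr = A(DBP)/MA`.
#'
#' @param owe a fitted `owe`.
#' @param rs_sbp,rs_dbp reference pressures, mmHg; must satisfy
#'   `rs_dbp < MAP < rs_sbp` and lie inside the envelope domain.
#' @return list of class `ratio_pair` with elements `sbpr`, `dbpr`.
#' @export
reference_ratios <- function(owe, rs_sbp, rs_dbp) {
  if (is.null(owe$spline)) stop("envelope must be fitted")
  if (!(rs_dbp < owe$map && owe$map < rs_sbp))
    stop("reference pressures must straddle the envelope maximum ",
         "(rs_dbp < MAP < rs_sbp)")
  dom <- range(owe$knots$cp)
  if (rs_sbp > dom[2] + 1e-9 || rs_dbp < dom[1] - 1e-9)
    stop("reference pressure outside the envelope domain")
  structure(list(sbpr = owe_eval(owe, rs_sbp) / owe$ma,
                 dbpr = owe_eval(owe, rs_dbp) / owe$ma),
            class = "ratio_pair")
}
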