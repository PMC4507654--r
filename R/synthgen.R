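#' Configuration for the synthetic cuff-recording simulator
#'
#' Builds and validates the parameter set of the cuff-deflation simulator.
#' Recordings consist of a linear deflation ramp from `cp_start` to `cp_end`,
#' heart-beat-locked raised-cosine oscillometric pulses scaled by a skewed
#' amplitude envelope that peaks at the true mean arterial pressure (MAP),
#' optional movement artifacts, and additive white sensor noise.
#'
#' The envelope is a two-sided generalized Gaussian in the cuff-pressure
#' domain: `A(cp) = MA * exp(-(|cp - MAP| / w)^p)` with independent widths
#' `w` on the high-pressure (systolic) and low-pressure (diastolic) sides.
#' The side widths are `wr = a * width_total` and `wl = (1 - a) * width_total`
#' where the asymmetry `a` is drawn uniformly from `asym_range`. The true
#' characteristic ratios are tied to the asymmetry through `ratio_link`
#' (`sbpr = intercept + slope * a + noise`, likewise for `dbpr`), and the
#' true SBP/DBP are then placed where the envelope attains `sbpr * MA`
#' (high side) and `dbpr * MA` (low side), so the generated envelope is
#' exactly consistent with the recorded ground truth. Draws whose implied
#' pressures fall outside `sbp_range`/`dbp_range` are rejected and redrawn.
#'
#' @param n_recordings number of recordings in a cohort.
#' @param sbp_range,dbp_range admissible systolic / diastolic pressure ranges
#'   (mmHg); draws outside these are rejected.
#' @param hr_range heart-rate range, beats/min; one rate per recording.
#' @param deflation_rate_range linear cuff-deflation rate range, mmHg/s.
#' @param cp_start,cp_end cuff pressure at the start / end of deflation (mmHg).
#' @param fs sampling rate, Hz.
#' @param envelope_shape list with `width_total` (mmHg), `asym_range`,
#'   `exponent` (generalized-Gaussian shape), `ma_range` (maximum envelope
#'   amplitude, mmHg), `map_range` (mmHg) and `pulse_width_s` (raised-cosine
#'   pulse duration, s).
#' @param ratio_link list with `sbpr = c(intercept, slope)`,
#'   `dbpr = c(intercept, slope)` linking the true ratios to the drawn
#'   envelope asymmetry, and `noise_sd`, the SD of Gaussian link noise.
#' @param sensor_noise_sd SD of additive white sensor noise, mmHg.
#' @param artifact_spec list of artifacts applied to every recording; each
#'   element is `list(kind =, at =, magnitude =)` as in [inject_artifact()].
#' @param recordings_per_subject consecutive recordings sharing a subject id.
#' @param seed integer seed; together with the draw index it fully determines
#'   each recording.
#' @return an object of class `synth_config`.
#' @seealso [generate_recording()], [generate_cohort()], [inject_artifact()]
#' @export
synth_config <- function(n_recordings = 1L,
                         sbp_range = c(70, 133),
                         dbp_range = c(42, 88),
                         hr_range = c(60, 90),
                         deflation_rate_range = c(2, 3),
                         cp_start = 180,
                         cp_end = 40,
                         fs = 1000,
                         envelope_shape = list(),
                         ratio_link = list(),
                         sensor_noise_sd = 0.02,
                         artifact_spec = list(),
                         recordings_per_subject = 4L,
                         seed = 1L) {
  shape_default <- list(width_total = 50, asym_range = c(0.35, 0.65),
                        exponent = 1.5, ma_range = c(1.5, 3),
                        map_range = c(75, 94), pulse_width_s = 0.35)
  link_default <- list(sbpr = c(intercept = 0.75, slope = -0.5),
                       dbpr = c(intercept = 0.45, slope = 0.5),
                       noise_sd = 0.01)
  envelope_shape <- utils::modifyList(shape_default, envelope_shape)
  ratio_link <- utils::modifyList(link_default, ratio_link)

  cfg <- list(n_recordings = as.integer(n_recordings),
              sbp_range = sbp_range, dbp_range = dbp_range,
              hr_range = hr_range,
              deflation_rate_range = deflation_rate_range,
              cp_start = cp_start, cp_end = cp_end, fs = fs,
              envelope_shape = envelope_shape, ratio_link = ratio_link,
              sensor_noise_sd = sensor_noise_sd,
              artifact_spec = artifact_spec,
              recordings_per_subject = as.integer(recordings_per_subject),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_recordings >= 1L, cfg$fs > 0,
            cfg$sensor_noise_sd >= 0,
            length(cfg$sbp_range) == 2L, length(cfg$dbp_range) == 2L)
  if (cfg$cp_start <= max(cfg$sbp_range))
    stop("configuration error: cp_start must exceed the upper SBP bound")
  if (cfg$cp_end >= min(cfg$dbp_range))
    stop("configuration error: cp_end must lie below the lower DBP bound")
  if (cfg$fs <= 2 * max(cfg$hr_range) / 60)
    stop("configuration error: fs must exceed twice the maximum heart rate")
  if (min(cfg$deflation_rate_range) <= 0)
    stop("configuration error: deflation rate must be positive")
  invisible(cfg)
}

#' Two-sided generalized-Gaussian envelope
#'
#' Amplitude of the simulator's oscillometric envelope at cuff pressure `cp`.
#' Independent widths on the high-pressure (`wr`) and low-pressure (`wl`)
#' sides of the maximum produce the skewed envelopes seen in real deflation
#' recordings.
#'
#' @param cp cuff pressure(s), mmHg.
#' @param map cuff pressure of the envelope maximum, mmHg.
#' @param ma maximum amplitude, mmHg.
#' @param wl,wr low- / high-pressure side widths, mmHg.
#' @param p shape exponent (2 = Gaussian; < 2 heavier tails).
#' @return envelope amplitude(s), mmHg.
#' @export
gg_envelope <- function(cp, map, ma, wl, wr, p) {
  d <- cp - map
  w <- ifelse(d > 0, wr, wl)
  ma * exp(-(abs(d) / w)^p)
}

## One deterministic substream per (seed, draw_index, purpose).
rec_seed <- function(seed, draw_index, offset = 0L) {
  as.integer((as.double(seed) * 48271 + draw_index * 69621 + offset * 16807) %%
               2147483399)
}

draw_recording_params <- function(cfg, draw_index) {
  set.seed(rec_seed(cfg$seed, draw_index))
  sh <- cfg$envelope_shape
  lk <- cfg$ratio_link
  for (try in seq_len(200L)) {
    a <- stats::runif(1, sh$asym_range[1], sh$asym_range[2])
    map <- stats::runif(1, sh$map_range[1], sh$map_range[2])
    ma <- stats::runif(1, sh$ma_range[1], sh$ma_range[2])
    hr <- stats::runif(1, cfg$hr_range[1], cfg$hr_range[2])
    rate <- stats::runif(1, cfg$deflation_rate_range[1],
                         cfg$deflation_rate_range[2])
    sbpr <- lk$sbpr[[1]] + lk$sbpr[[2]] * a + stats::rnorm(1, 0, lk$noise_sd)
    dbpr <- lk$dbpr[[1]] + lk$dbpr[[2]] * a + stats::rnorm(1, 0, lk$noise_sd)
    if (sbpr <= 0.05 || sbpr >= 0.98 || dbpr <= 0.05 || dbpr >= 0.98) next
    wr <- a * sh$width_total
    wl <- (1 - a) * sh$width_total
    p <- sh$exponent
    sbp <- map + wr * (-log(sbpr))^(1 / p)
    dbp <- map - wl * (-log(dbpr))^(1 / p)
    ok <- sbp >= cfg$sbp_range[1] && sbp <= cfg$sbp_range[2] &&
      dbp >= cfg$dbp_range[1] && dbp <= cfg$dbp_range[2] &&
      dbp < map && map < sbp &&
      cfg$cp_start > sbp && cfg$cp_end < dbp
    if (ok)
      return(list(a = a, map = map, ma = ma, hr = hr, rate = rate,
                  sbpr = sbpr, dbpr = dbpr, wl = wl, wr = wr, p = p,
                  sbp = sbp, dbp = dbp))
  }
  stop("configuration error: could not draw feasible SBP/DBP within the ",
       "configured ranges (ratio_link and envelope_shape are inconsistent ",
       "with sbp_range/dbp_range)")
}

#' Generate one synthetic cuff recording with ground truth
#'
#' Deterministic given `(config$seed, draw_index)`. The returned recording
#' holds the composite cuff-pressure signal (ramp + envelope-scaled pulses +
#' artifacts + noise) with R-peak annotations at each pulse onset; the ground
#' truth records the drawn SBP/DBP/MAP, the true characteristic ratios, the
#' envelope parameters and any artifact intervals.
#'
#' @param config a [synth_config()].
#' @param draw_index 1-based index of the draw within the cohort.
#' @return list with elements `recording` (class `cuff_recording`) and
#'   `truth` (class `bp_ground_truth`).
#' @export
generate_recording <- function(config, draw_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  pr <- draw_recording_params(config, draw_index)
  fs <- config$fs
  dur <- (config$cp_start - config$cp_end) / pr$rate
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  cp <- config$cp_start - pr$rate * t

  rr <- 60 / pr$hr
  tp_w <- min(config$envelope_shape$pulse_width_s, 0.9 * rr)
  beat_t <- seq(0.3, dur - tp_w - 0.05, by = rr)
  if (length(beat_t) < 6L)
    stop("configuration error: deflation window too short to span SBP->DBP")
  apex_cp <- config$cp_start - pr$rate * (beat_t + tp_w / 2)
  amp <- gg_envelope(apex_cp, pr$map, pr$ma, pr$wl, pr$wr, pr$p)
  for (k in seq_along(beat_t)) {
    i0 <- floor(beat_t[k] * fs) + 1L
    i1 <- min(n, floor((beat_t[k] + tp_w) * fs))
    idx <- i0:i1
    cp[idx] <- cp[idx] +
      amp[k] * 0.5 * (1 - cos(2 * pi * (t[idx] - beat_t[k]) / tp_w))
  }

  r_peaks <- pmin(n, floor(beat_t * fs) + 1L)
  synth_meta <- list(params = pr, beat_t = beat_t, pulse_width_s = tp_w,
                     pulse_amp = amp, duration_s = dur)
  rec <- cuff_recording(cp = cp, fs = fs, r_peaks = r_peaks,
                        reference_sbp = pr$sbp, reference_dbp = pr$dbp,
                        meta = list(id = sprintf("synth-%04d", draw_index),
                                    subject = (draw_index - 1L) %/%
                                      config$recordings_per_subject + 1L,
                                    synth = synth_meta,
                                    artifact_intervals = list()))

  for (j in seq_along(config$artifact_spec)) {
    sp <- config$artifact_spec[[j]]
    rec <- inject_artifact(rec, sp$kind, sp$at, sp$magnitude,
                           seed = rec_seed(config$seed, draw_index, j))
  }
  if (config$sensor_noise_sd > 0) {
    set.seed(rec_seed(config$seed, draw_index, 9001L))
    rec$cp <- rec$cp + stats::rnorm(n, 0, config$sensor_noise_sd)
  }

  truth <- structure(
    list(sbp = pr$sbp, dbp = pr$dbp, map = pr$map,
         sbpr = pr$sbpr, dbpr = pr$dbpr, ma = pr$ma,
         wl = pr$wl, wr = pr$wr, exponent = pr$p, asymmetry = pr$a,
         hr = pr$hr, deflation_rate = pr$rate,
         pulse_times = beat_t,
         artifact_intervals = rec$meta$artifact_intervals),
    class = "bp_ground_truth")
  list(recording = rec, truth = truth)
}

#' Generate a cohort of synthetic recordings
#'
#' Calls [generate_recording()] for draw indices `1:n_recordings`; each draw
#' uses its own deterministic substream, so the cohort is reproducible under
#' a fixed seed and individual recordings can be regenerated in isolation.
#'
#' @param config a [synth_config()] with `n_recordings >= 1`.
#' @return list of `list(recording, truth)` pairs.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$n_recordings >= 1L)
  lapply(seq_len(config$n_recordings),
         function(i) generate_recording(config, i))
}

#' Inject a movement artifact into a cuff recording
#'
#' Four signal-level archetypes cover the movement classes used in supervised
#' contamination protocols (arm lifts/bends, tapping, finger squeezing,
#' shaking, cuff removal):
#' \describe{
#'   \item{`pressure-bump`}{slow transient cuff-pressure rise of `magnitude`
#'     mmHg: 0.5 s rise, 1 s hold, 2 s release (interval 3.5 s).}
#'   \item{`amplitude-spike`}{the oscillometric pulse whose span contains
#'     `at` is scaled by `1 + magnitude` (so `magnitude = 0.8` gives a
#'     1.8-fold pulse); requires simulator metadata.}
#'   \item{`burst-oscillation`}{added 3.5 Hz broadband burst of amplitude
#'     `magnitude` mmHg under a 1.5 s raised-cosine window, random phase.}
#'   \item{`cuff-release`}{from `at` onward the pressure collapses toward
#'     the end pressure with a 0.3 s time constant; `magnitude` in \[0, 1\]
#'     mixes between the intact and fully collapsed trajectories.}
#' }
#' `magnitude = 0` returns the input unchanged (apart from provenance).
#' Samples outside the declared artifact interval are bit-identical to the
#' input.
#'
#' @param rec a `cuff_recording`.
#' @param kind artifact archetype, one of the four above.
#' @param at artifact onset time, s.
#' @param magnitude archetype-specific scale (see above).
#' @param seed integer seed for the artifact's own randomness (burst phase).
#' @return a modified copy of `rec` with the artifact interval appended to
#'   `meta$artifact_intervals`.
#' @export
inject_artifact <- function(rec, kind, at, magnitude, seed = 1L) {
  stopifnot(inherits(rec, "cuff_recording"))
  n <- length(rec$cp)
  fs <- rec$fs
  t_end <- (n - 1) / fs
  if (at < 0 || at > t_end) stop("artifact time 'at' outside the recording")
  t <- (seq_len(n) - 1) / fs
  out <- rec

  if (kind == "pressure-bump") {
    rise <- 0.5; hold <- 1; fall <- 2
    sstep <- function(z) ifelse(z <= 0, 0, ifelse(z >= 1, 1,
                                                  0.5 * (1 - cos(pi * z))))
    out$cp <- rec$cp + magnitude * (sstep((t - at) / rise) -
                                      sstep((t - at - rise - hold) / fall))
    interval <- c(at, min(t_end, at + rise + hold + fall))
  } else if (kind == "amplitude-spike") {
    sm <- rec$meta$synth
    if (is.null(sm))
      stop("amplitude-spike injection needs simulator pulse metadata")
    k <- findInterval(at, sm$beat_t)
    if (k < 1L) stop("'at' precedes the first pulse")
    i0 <- floor(sm$beat_t[k] * fs) + 1L
    i1 <- min(n, floor((sm$beat_t[k] + sm$pulse_width_s) * fs))
    idx <- i0:i1
    out$cp[idx] <- rec$cp[idx] + magnitude * sm$pulse_amp[k] * 0.5 *
      (1 - cos(2 * pi * (t[idx] - sm$beat_t[k]) / sm$pulse_width_s))
    rr_end <- if (k < length(sm$beat_t)) sm$beat_t[k + 1L] else t_end
    interval <- c(sm$beat_t[k], rr_end)
  } else if (kind == "burst-oscillation") {
    width <- 1.5
    set.seed(seed)
    phase <- stats::runif(1, 0, 2 * pi)
    win <- ifelse(t >= at & t <= at + width,
                  0.5 * (1 - cos(2 * pi * (t - at) / width)), 0)
    out$cp <- rec$cp + magnitude * win * cos(2 * pi * 3.5 * t + phase)
    interval <- c(at, min(t_end, at + width))
  } else if (kind == "cuff-release") {
    tail_i <- t > at
    collapsed <- min(rec$cp) + (rec$cp[max(which(!tail_i))] - min(rec$cp)) *
      exp(-(t[tail_i] - at) / 0.3)
    out$cp[tail_i] <- (1 - magnitude) * rec$cp[tail_i] + magnitude * collapsed
    interval <- c(at, t_end)
  } else {
    stop("unknown artifact kind: ", kind)
  }
  if (magnitude == 0) out$cp <- rec$cp
  out$meta$artifact_intervals <-
    c(rec$meta$artifact_intervals,
      list(list(kind = kind, interval = interval, magnitude = magnitude)))
  out
}
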