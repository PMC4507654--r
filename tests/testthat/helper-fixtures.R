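# Fixtures are generated in code; expensive ones are cached for the session.

.fix_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fix_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fix_cache)
  get(key, envir = .fix_cache, inherits = FALSE)
}

# Noise-free single recording plus ground truth.
clean_recording <- function(seed) {
  cached_fixture(paste0("clean-", seed), {
    generate_recording(synth_config(sensor_noise_sd = 0, seed = seed), 1L)
  })
}

# Noise-free recording with ×1.8 amplitude spikes on n_spikes pulses;
# returns recording, truth, and the spiked pulse onset times.
spiked_recording <- function(seed, n_spikes = 4, factor_excess = 0.8) {
  cached_fixture(paste0("spiked-", seed, "-", n_spikes), {
    g <- clean_recording(seed)
    rec <- g$recording
    dur <- rec$meta$synth$duration_s
    set.seed(seed)
    ats <- sort(runif(n_spikes, 6, dur - 6))
    for (at in ats)
      rec <- inject_artifact(rec, "amplitude-spike", at, factor_excess,
                             seed = seed)
    beat_t <- g$recording$meta$synth$beat_t
    spike_beats <- vapply(ats, function(at) findInterval(at, beat_t),
                          numeric(1))
    list(recording = rec, truth = g$truth,
         spike_onsets = beat_t[spike_beats])
  })
}

# Random smooth skewed envelope sampled at deflation knots, with the
# parameters attached for round-trip checks.
random_owe <- function(seed) {
  set.seed(seed)
  map <- runif(1, 75, 94)
  ma <- runif(1, 1.5, 3)
  wl <- runif(1, 18, 33)
  wr <- runif(1, 18, 33)
  p <- 1.5
  rate <- runif(1, 2, 3)
  cp <- seq(45, 175, by = runif(1, 2, 3))
  owe <- fit_spline(data.frame(cp = cp,
                               amplitude = gg_envelope(cp, map, ma, wl, wr, p),
                               t = (180 - cp) / rate))
  attr(owe, "params") <- list(map = map, ma = ma, wl = wl, wr = wr, p = p,
                              rate = rate)
  owe
}

# Piecewise-linear triangular envelope with a dense knot grid so the cubic
# interpolant is indistinguishable from the triangle away from the apex.
triangle_owe <- function(apex_cp = 100, apex_amp = 3, lo = 50, hi = 140,
                         step = 2, rate = 2.5) {
  cp <- sort(unique(c(seq(lo, hi, by = step), apex_cp)))
  amp <- apex_amp * pmin((hi - cp) / (hi - apex_cp),
                         (cp - lo) / (apex_cp - lo))
  suppressWarnings(fit_spline(data.frame(cp = cp, amplitude = pmax(amp, 0),
                                         t = (180 - cp) / rate)))
}

# Symmetric smooth envelope (Gaussian about 100 mmHg on a symmetric grid).
symmetric_owe <- function(width = 25, rate = 2.5) {
  cp <- seq(60, 140, by = 2)
  fit_spline(data.frame(cp = cp,
                        amplitude = 2.5 * exp(-((cp - 100) / width)^2),
                        t = (180 - cp) / rate))
}

# Feature-level cohort with signal planted in (ratio2, area3) only; every
# recording shares one triangular envelope, and the reference pressures are
# obtained by inverting the true ratios on it.
toy_cohort <- function(seed, n = 40, planted = TRUE) {
  tri <- cached_fixture("toy-triangle", triangle_owe())
  set.seed(seed)
  f <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(f) <- bp_feature_names
  sbpr <- if (planted)
    0.55 + 0.1 * f$ratio2 + 0.05 * f$area3 + rnorm(n, 0, 0.003)
  else
    0.55 + rnorm(n, 0, 0.003)
  dbpr <- 0.7 + 0.05 * f$ratio2 + rnorm(n, 0, 0.003)
  sbpr <- pmin(pmax(sbpr, 0.1), 0.95)
  dbpr <- pmin(pmax(dbpr, 0.1), 0.95)
  ref <- vapply(seq_len(n), function(i) {
    e <- estimate_bp_from_ratios(
      tri, structure(list(sbpr = sbpr[i], dbpr = dbpr[i]),
                     class = "ratio_pair"))
    c(e$sbp, e$dbp)
  }, numeric(2))
  bp_cohort(f, rep(list(tri), n), ref[1, ], ref[2, ], sbpr, dbpr,
            subject = rep(seq_len(n %/% 4), each = 4, length.out = n))
}

# Constant-height pulse table for unit tests of the outlier rules.
flat_pulses <- function(n = 10, peak = 1, bottom = -1) {
  out <- data.frame(start = seq_len(n) * 1000L,
                    end = seq_len(n) * 1000L + 1000L,
                    peak_idx = seq_len(n) * 1000L + 500L,
                    t_peak = seq_len(n) + 0.5,
                    peak_value = peak, bottom_value = bottom,
                    pk2bt_prev = peak - bottom, pk2bt_next = peak - bottom,
                    cp_at_peak = 150 - 2.5 * seq_len(n),
                    outlier = FALSE, reason = NA_character_)
  class(out) <- c("bp_pulses", "data.frame")
  out
}
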