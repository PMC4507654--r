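test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_recordings = 3, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$recording$cp, b[[i]]$recording$cp)
    expect_identical(a[[i]]$recording$r_peaks, b[[i]]$recording$r_peaks)
    expect_identical(a[[i]]$truth$sbp, b[[i]]$truth$sbp)
  }
  # single-recording regeneration matches its cohort element
  expect_identical(generate_recording(cfg, 2)$recording$cp,
                   a[[2]]$recording$cp)
})

test_that("deflation ramp spans the configured pressures at the stated rate", {
  g <- clean_recording(1)
  cp <- g$recording$cp
  expect_lt(abs(cp[1] - 180), 2)
  expect_lt(abs(cp[length(cp)] - 40), 2)

  # least-squares slope of the low-passed pressure, edges trimmed
  fs <- g$recording$fs
  bl <- lowpass_cuff_baseline(cp, fs)
  i <- seq(3 * fs, length(cp) - 3 * fs)
  slope <- coef(lm(bl[i] ~ I(i / fs)))[2]
  expect_gte(slope, -3)
  expect_lte(slope, -2)
})

test_that("drawn pressures respect the configured ranges and orderings", {
  cfg <- synth_config(n_recordings = 40, seed = 7)
  cohort <- generate_cohort(cfg)
  sbp <- vapply(cohort, function(g) g$truth$sbp, numeric(1))
  dbp <- vapply(cohort, function(g) g$truth$dbp, numeric(1))
  map <- vapply(cohort, function(g) g$truth$map, numeric(1))
  expect_true(all(sbp >= 70 & sbp <= 133))
  expect_true(all(dbp >= 42 & dbp <= 88))
  expect_true(all(dbp < map & map < sbp))
})

test_that("ratio link is exactly linear in the asymmetry when noiseless", {
  cfg <- synth_config(n_recordings = 5, seed = 3,
                      ratio_link = list(noise_sd = 0))
  for (g in generate_cohort(cfg)) {
    a <- g$truth$asymmetry
    expect_equal(g$truth$sbpr, 0.75 - 0.5 * a, tolerance = 1e-12)
    expect_equal(g$truth$dbpr, 0.45 + 0.5 * a, tolerance = 1e-12)
  }
})

test_that("generator envelope is consistent with the recorded ground truth", {
  for (seed in 1:5) {
    tr <- clean_recording(seed)$truth
    expect_equal(gg_envelope(tr$sbp, tr$map, tr$ma, tr$wl, tr$wr,
                             tr$exponent) / tr$ma,
                 tr$sbpr, tolerance = 1e-9)
    expect_equal(gg_envelope(tr$dbp, tr$map, tr$ma, tr$wl, tr$wr,
                             tr$exponent) / tr$ma,
                 tr$dbpr, tolerance = 1e-9)
  }
})

test_that("infeasible configurations raise a configuration error", {
  expect_error(synth_config(fs = 1), "configuration error")
  expect_error(synth_config(cp_start = 120), "configuration error")
  expect_error(synth_config(cp_end = 50), "configuration error")
  cfg <- synth_config(envelope_shape = list(width_total = 220), seed = 1)
  expect_error(generate_recording(cfg, 1), "configuration error")
})

test_that("noise-free clean pipeline recovers the configured MAP", {
  for (seed in c(2, 9)) {
    g <- clean_recording(seed)
    pr <- process_recording(g$recording, artifact_removal = FALSE)
    expect_lt(abs(pr$owe$map - g$truth$map), 2)
  }
})

test_that("artifacts are local: samples outside the interval are untouched", {
  g <- clean_recording(4)
  rec <- g$recording
  fs <- rec$fs
  for (kind in c("pressure-bump", "burst-oscillation", "amplitude-spike")) {
    mod <- inject_artifact(rec, kind, at = 20, magnitude = 0.8, seed = 1)
    iv <- mod$meta$artifact_intervals[[1]]$interval
    outside <- c(seq_len(floor(iv[1] * fs)),
                 seq(ceiling(iv[2] * fs) + 2, length(rec$cp)))
    expect_identical(mod$cp[outside], rec$cp[outside])
    expect_false(identical(mod$cp, rec$cp))
  }
  rel <- inject_artifact(rec, "cuff-release", at = 30, magnitude = 1)
  before <- seq_len(30 * fs)
  expect_identical(rel$cp[before], rec$cp[before])
  expect_lt(rel$cp[35 * fs], rec$cp[35 * fs])
})

test_that("zero-magnitude artifacts leave the signal identical", {
  rec <- clean_recording(4)$recording
  for (kind in c("pressure-bump", "amplitude-spike", "burst-oscillation",
                 "cuff-release"))
    expect_identical(inject_artifact(rec, kind, 20, 0)$cp, rec$cp)
  expect_error(inject_artifact(rec, "teleport", 20, 1), "unknown artifact")
  expect_error(inject_artifact(rec, "pressure-bump", 1e6, 1), "outside")
})

test_that("a pressure bump raises the cuff pressure during deflation", {
  rec <- clean_recording(5)$recording
  mod <- inject_artifact(rec, "pressure-bump", at = 20, magnitude = 8)
  fs <- rec$fs
  iv <- mod$meta$artifact_intervals[[1]]$interval
  idx <- seq(floor(iv[1] * fs) + 1, ceiling(iv[2] * fs))
  bl <- lowpass_cuff_baseline(mod$cp, fs)
  expect_true(any(diff(bl[idx]) > 0))
})

test_that("an amplitude spike makes the pulse stand out from its neighbours", {
  sp <- spiked_recording(21, n_spikes = 1)
  rec <- sp$recording
  omw <- detrend_oscillometric(rec$cp, rec$fs)
  pulses <- segment_pulses(omw, rec)
  k <- which(abs(pulses$t_peak - (sp$spike_onsets[1] +
                                    rec$meta$synth$pulse_width_s / 2)) ==
               min(abs(pulses$t_peak - (sp$spike_onsets[1] +
                                          rec$meta$synth$pulse_width_s / 2))))
  nb <- setdiff(max(1, k - 2):min(nrow(pulses), k + 2), k)
  expect_gt(pulses$pk2bt_prev[k], 1.5 * median(pulses$pk2bt_prev[nb]))
})
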