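# Pes with scripted cardiogenic ripple + slow respiratory component
make_pes_mix <- function(ripple_amp = 1, resp_amp = 5, dur = 60, rate = 100,
                         seed = 11) {
  set.seed(seed)
  t <- (seq_len(dur * rate) - 1) / rate
  resp <- resp_amp * sin(2 * pi * 0.25 * t)
  tpl <- ventsync:::qrs_template(rate, width_s = 0.24)
  beats <- seq(0.5, dur - 0.5, by = 0.8)
  ripple <- numeric(length(t))
  half <- (length(tpl) - 1) %/% 2
  for (b in beats) {
    c0 <- round(b * rate) + 1
    ripple[(c0 - half):(c0 + half)] <- ripple[(c0 - half):(c0 + half)] +
      ripple_amp * tpl
  }
  list(ts = time_series(resp + ripple, rate, units = "cmH2O"),
       resp = resp, ripple = ripple, beats = beats)
}

test_that("cardiogenic Pes artifacts are suppressed, respiration preserved", {
  mix <- make_pes_mix()
  out <- suppress_pes_cardiac(mix$ts, beat_times = mix$beats)
  resid <- out$samples - mix$resp
  expect_lt(mean(resid^2) / mean(mix$ripple^2), 0.20)  # >=80% ripple power cut
  resp_out <- ventsync:::fft_bandpass(out$samples, 100, high = 2)
  resp_in <- ventsync:::fft_bandpass(mix$ts$samples, 100, high = 2)
  expect_lt(sqrt(mean((resp_out - resp_in)^2)) / sqrt(mean(resp_in^2)), 0.05)

  # ripple-free input unchanged within 2% RMS
  clean <- time_series(mix$resp, 100, units = "cmH2O")
  out2 <- suppressWarnings(suppress_pes_cardiac(clean))
  expect_lt(sqrt(mean((out2$samples - clean$samples)^2)) /
              sqrt(mean(clean$samples^2)), 0.02)

  # ripple-only input mostly nulled
  rip <- time_series(mix$ripple, 100, units = "cmH2O")
  out3 <- suppress_pes_cardiac(rip, beat_times = mix$beats)
  expect_lt(sqrt(mean(out3$samples^2)), 0.20 * sqrt(mean(rip$samples^2)))
})

test_that("flow integrates to drift-corrected volume", {
  # square flow: +0.5 L/s for 1 s, -0.5 L/s for 1 s
  sq <- time_series(c(rep(0.5, 100), rep(-0.5, 100)), 100, units = "L/s")
  V <- integrate_flow(sq, drift_correct = FALSE)
  expect_equal(V$units, "L")
  expect_equal(max(V$samples), 0.5, tolerance = 0.02)
  expect_equal(V$samples[length(V$samples)], 0, tolerance = 0.01)

  expect_equal(integrate_flow(time_series(rep(0, 500), 100))$samples,
               rep(0, 500))

  # synthetic breath train with a 0.01 L/s sensor offset: drift correction
  # keeps end-expiratory volume within +/- 0.02 L of zero
  cfg <- scenario_config(duration = 62, event_mix = c(synchronous = 1),
                         seed = 12)
  g <- generate_recording(cfg)
  flow <- g$recording$channels$flow
  biased <- time_series(flow$samples + 0.01, flow$rate, units = "L/s")
  V2 <- integrate_flow(biased)
  ends <- g$truth$effort_on[-1] - 0.05
  idx <- round(ends * flow$rate) + 1
  expect_lt(max(abs(V2$samples[idx])), 0.02)
})

test_that("chest-wall elastance is recovered from passive intervals", {
  # exact linear relation Pes = 4 V + 2 -> Ecw 4, baseline 2
  t <- seq(0, 10 - 0.01, by = 0.01)
  V <- time_series(pmax(0, 0.4 * sin(2 * pi * 0.25 * t)), 100, units = "L")
  pes <- time_series(4 * V$samples + 2, 100, units = "cmH2O")
  cw <- estimate_ecw(pes, V, matrix(c(0, 10), ncol = 2))
  expect_equal(cw$ecw, 4, tolerance = 1e-6)
  expect_equal(cw$pes_baseline, 2, tolerance = 1e-6)

  # degenerate: constant volume
  Vc <- time_series(rep(0.2, 1000), 100, units = "L")
  expect_error(estimate_ecw(pes, Vc, matrix(c(0, 10), ncol = 2)),
               "degenerate")
  expect_error(estimate_ecw(pes, V, NULL), "passive")

  # generator oracle: passive breaths with Ecw 5 -> estimate within 0.25
  cfg <- scenario_config(duration = 62, event_mix = c(auto_trigger = 1),
                         seed = 13)
  g <- generate_recording(cfg)
  pesf <- suppress_pes_cardiac(g$recording$channels$pes,
                               beat_times = g$recording$meta$ecg_beats)
  vol <- integrate_flow(g$recording$channels$flow)
  cw2 <- estimate_ecw(pesf, vol, passive_intervals(g$truth, 62))
  expect_equal(cw2$ecw, 5, tolerance = 0.25 / 5)
  expect_equal(cw2$pes_baseline, g$recording$meta$pes_baseline,
               tolerance = 0.15)
})

test_that("Pmus derivation recovers scripted efforts and passive nulls", {
  # closed form: Pes == baseline, V == 0 -> Pmus == 0
  z <- time_series(rep(0, 200), 100)
  b3 <- time_series(rep(3, 200), 100)
  cw <- structure(list(ecw = 5, pes_baseline = 3), class = "chest_wall_model")
  expect_equal(derive_pmus(b3, z, cw)$samples, rep(0, 200))
  expect_error(derive_pmus(b3, time_series(rep(0, 200), 50), cw),
               "misaligned")

  # passive synthetic breaths: |Pmus| stays < 0.5 cmH2O
  cfg <- scenario_config(duration = 62, event_mix = c(auto_trigger = 1),
                         seed = 14)
  g <- generate_recording(cfg)
  pesf <- suppress_pes_cardiac(g$recording$channels$pes,
                               beat_times = g$recording$meta$ecg_beats)
  vol <- integrate_flow(g$recording$channels$flow)
  cw2 <- estimate_ecw(pesf, vol, passive_intervals(g$truth, 62))
  pmus <- derive_pmus(pesf, vol, cw2)
  mid <- seq(200, length(pmus$samples) - 200)   # skip filter edges
  expect_lt(max(abs(pmus$samples[mid])), 0.5)

  # scripted 8 cmH2O effort: peak Pmus recovered within 10%
  cfg2 <- scenario_config(duration = 62, event_mix = c(synchronous = 1),
                          pes_effort_amplitude = 8, seed = 15)
  g2 <- generate_recording(cfg2)
  pesf2 <- suppress_pes_cardiac(g2$recording$channels$pes,
                                beat_times = g2$recording$meta$ecg_beats)
  vol2 <- integrate_flow(g2$recording$channels$flow)
  cw3 <- estimate_ecw(pesf2, vol2, passive_intervals(g2$truth, 62))
  pmus2 <- derive_pmus(pesf2, vol2, cw3)
  peaks <- vapply(which(!is.na(g2$truth$effort_on)), function(i) {
    i0 <- round(g2$truth$effort_on[i] * 100) + 1
    i1 <- round(g2$truth$effort_off[i] * 100) + 1
    max(pmus2$samples[i0:i1])
  }, numeric(1))
  expect_equal(mean(peaks), 8, tolerance = 0.10)
})

test_that("effort end on Pmus follows the 70% rule", {
  # triangular pulse: rise 0->10 over [1,2], fall 10->0 over [2,3]
  t <- seq(0, 4 - 0.01, by = 0.01)
  y <- pmax(0, 1 - abs(t - 2)) * 10
  pmus <- time_series(y, 100, units = "cmH2O")
  end <- effort_end_pmus(pmus, onset = 1, search_end = 3.5)
  expect_equal(as.numeric(end), 2.3, tolerance = 0.0101)

  # monotone rise to the bound -> bound returned
  mono <- time_series(t, 100)
  expect_equal(as.numeric(effort_end_pmus(mono, 0.5, 3)), 3)

  # noisy pulse equals the brute-force sample scan
  set.seed(16)
  noisy <- time_series(y + stats::rnorm(length(y), 0, 0.3), 100)
  got <- as.numeric(effort_end_pmus(noisy, 1, 3.5))
  want <- oracle_offset_scan(noisy$samples, 100, 0, 1, 3.5, baseline = 0)
  expect_equal(got, want)

  # degenerate flag on a non-positive segment
  flat <- time_series(rep(-1, 400), 100)
  res <- effort_end_pmus(flat, 1, 3)
  expect_true(attr(res, "degenerate"))
})
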