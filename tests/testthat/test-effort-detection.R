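# trapezoidal burst envelope on a flat baseline
trapezoid_env <- function(foot = 5, ramp = 0.5, plateau = 1, amp = 10,
                          base = 1, dur = 30, rate = 100) {
  t <- (seq_len(dur * rate) - 1) / rate
  y <- rep(base, length(t))
  up <- t >= foot & t < foot + ramp
  y[up] <- base + amp * (t[up] - foot) / ramp
  top <- t >= foot + ramp & t < foot + ramp + plateau
  y[top] <- base + amp
  down <- t >= foot + ramp + plateau & t < foot + 2 * ramp + plateau
  y[down] <- base + amp * (1 - (t[down] - foot - ramp - plateau) / ramp)
  time_series(y, rate)
}

test_that("triangle algorithm places the onset at the ramp foot", {
  env <- trapezoid_env(foot = 5.00)
  ev <- detect_triangle(env)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 5.00, tolerance = 0.011)
  expect_equal(ev$algorithm, "triangle")
})

test_that("triangle 40% amplitude rule suppresses small peaks", {
  env <- trapezoid_env(foot = 5)
  # second burst peaking at 30% of the window maximum
  env2 <- trapezoid_env(foot = 15, amp = 3)
  both <- time_series(pmax(env$samples, env2$samples), 100)
  ev <- detect_triangle(both)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - 5), 0.05)
  # a 50% peak is kept
  env3 <- trapezoid_env(foot = 15, amp = 5)
  both2 <- time_series(pmax(env$samples, env3$samples), 100)
  expect_equal(nrow(detect_triangle(both2)), 2)
})

test_that("triangle detection is invariant to envelope scaling", {
  set.seed(20)
  cfg <- scenario_config(duration = 62, event_mix = c(synchronous = 1),
                         seed = 20)
  g <- generate_recording(cfg)
  env <- compute_envelope(suppressWarnings(remove_cardiac(
    remove_powerline(g$recording$channels$emg_di, 50))))
  ev1 <- detect_triangle(env)
  env_k <- env
  env_k$samples <- env$samples * 7.3
  ev2 <- detect_triangle(env_k)
  expect_equal(ev1$onset, ev2$onset)
  expect_equal(ev1$offset, ev2$offset)
  expect_equal(ev2$peak_amp, 7.3 * ev1$peak_amp, tolerance = 1e-9)
})

test_that("flat envelopes yield no events from either detector", {
  flat <- time_series(rep(1, 3000) + 0.001 * sin(1:3000), 100)
  expect_equal(nrow(detect_triangle(flat)), 0)
  expect_equal(nrow(detect_adaptive(flat)), 0)
})

test_that("adaptive threshold finds step onsets within the sustain time", {
  base <- rep(1, 1000)
  y <- c(base, rep(10, 300), base, rep(10, 300), base, rep(10, 300), base)
  env <- time_series(y, 100)
  ev <- detect_adaptive(env)
  expect_equal(nrow(ev), 3)
  steps <- c(1000, 2300, 3600) / 100
  expect_true(all(abs(ev$onset - steps) <= 0.06 + 0.011))
})

test_that("adaptive threshold tracks a slowly rising noise floor", {
  set.seed(21)
  n <- 12000                                  # 120 s at 100 Hz
  floor_lvl <- seq(1, 2, length.out = n)      # doubling noise floor
  env <- time_series(floor_lvl * (1 + 0.05 * stats::rnorm(n)), 100)
  ev <- detect_adaptive(env)
  expect_equal(nrow(ev), 0)
})

test_that("adaptive catches small bursts that the triangle 40% rule drops", {
  # one large burst dominates the window; small bursts at 3x the noise
  big <- trapezoid_env(foot = 3, amp = 15, base = 1, dur = 30)
  small1 <- trapezoid_env(foot = 12, amp = 2, base = 1, dur = 30)
  small2 <- trapezoid_env(foot = 22, amp = 2, base = 1, dur = 30)
  y <- pmax(big$samples, small1$samples, small2$samples)
  env <- time_series(y, 100)
  tri <- detect_triangle(env)
  ada <- detect_adaptive(env)
  expect_equal(nrow(tri), 1)                  # only the large burst
  expect_gte(nrow(ada), 3)                    # all three
})

test_that("envelope offset rule matches the analytic triangle and a scan", {
  # symmetric triangular burst 0 -> 10 -> 0 over [0, 2], baseline 0
  t <- seq(0, 4 - 0.01, by = 0.01)
  y <- pmax(0, 1 - abs(t - 1)) * 10
  env <- time_series(y, 100)
  end <- effort_end_envelope(env, onset = 0.01, bound = 3)
  expect_equal(end, 1.3, tolerance = 0.011)

  # plateau that never falls below 70% -> bound returned
  plat <- time_series(c(rep(0, 100), rep(10, 300)), 100)
  expect_equal(effort_end_envelope(plat, 1, 3.99), 3.99)

  # noisy burst equals brute-force scan with the same baseline definition
  set.seed(22)
  yn <- y + abs(stats::rnorm(length(y), 0, 0.2))
  envn <- time_series(yn, 100)
  got <- effort_end_envelope(envn, 0.3, 3)
  i0 <- ventsync:::ts_index(envn, 0.3)
  ib <- ventsync:::ts_index(envn, 0.3 - 0.25)
  base <- stats::median(envn$samples[ib:i0])
  want <- oracle_offset_scan(envn$samples, 100, 0, 0.3, 3, baseline = base)
  expect_equal(got, want)
})

test_that("channel fusion keeps the earlier onset and merges transitively", {
  a <- effort_events(c(1.00, 5.0), c(2.0, 6.0), source = "emg_di")
  b <- effort_events(1.05, 2.1, source = "emg_para")
  f <- fuse_channels(a, b)
  expect_equal(nrow(f), 2)
  expect_equal(f$onset[1], 1.00)
  expect_equal(f$offset[1], 2.1)
  expect_equal(f$source[1], "fused")
  expect_equal(f$source[2], "emg_di")          # unpaired kept as-is

  # empty list returns the other unchanged
  expect_equal(fuse_channels(a, effort_events()), a)
  expect_equal(fuse_channels(effort_events(), b), b)

  # chain: one a-event overlapping two b-events collapses into one span
  a2 <- effort_events(1.0, 3.0, source = "emg_di")
  b2 <- effort_events(c(0.8, 2.8), c(1.5, 3.5), source = "emg_para")
  f2 <- fuse_channels(a2, b2)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$onset, 0.8)
  expect_equal(f2$offset, 3.5)

  # touching at an endpoint is not an overlap
  a3 <- effort_events(1, 2)
  b3 <- effort_events(2, 3)
  expect_equal(nrow(fuse_channels(a3, b3)), 2)
})

test_that("detected events are ordered, non-overlapping, onset < offset", {
  cfg <- scenario_config(duration = 122,
                         event_mix = c(synchronous = 0.8, ineffective = 0.2),
                         seed = 23)
  g <- generate_recording(cfg)
  env <- compute_envelope(suppressWarnings(remove_cardiac(
    remove_powerline(g$recording$channels$emg_para, 50))))
  for (ev in list(detect_triangle(env), detect_adaptive(env))) {
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$offset > ev$onset))
    expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
    expect_true(all(ev$peak_time >= ev$onset & ev$peak_time <= ev$offset))
  }
})
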