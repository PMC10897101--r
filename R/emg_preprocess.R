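#' Remove powerline interference from an sEMG channel
#'
#' Zero-phase IIR notch at the mains frequency and all harmonics below
#' Nyquist (narrow -3 dB bandwidth so passband gain stays within 0.5 dB
#' outside +/- 2 Hz of each notch).
#'
#' @param emg A [time_series()] in uV.
#' @param mains_hz Mains frequency, 50 or 60 Hz.
#' @return Denoised `vent_ts`.
#' @export
remove_powerline <- function(emg, mains_hz = 50) {
  stopifnot(inherits(emg, "vent_ts"))
  if (emg$rate <= 2 * mains_hz)
    stop("sampling rate must exceed twice the mains frequency")
  x <- emg$samples
  if (all(x == 0)) return(emg)
  harmonics <- seq(mains_hz, emg$rate / 2 - 1, by = mains_hz)
  for (f0 in harmonics) {
    d <- design_notch(f0, bw = 0.8, rate = emg$rate)
    x <- filtfilt_pad(d$b, d$a, x)
  }
  time_series(x, emg$rate, emg$t0, emg$units)
}

# internal QRS detection: 5-30 Hz band-pass + adaptive amplitude threshold
detect_qrs <- function(emg) {
  y <- fft_bandpass(emg$samples, emg$rate, low = 5, high = 30)
  y <- abs(y)
  thr <- 4 * stats::median(y) / 0.6745
  min_dist <- round(0.25 * emg$rate)          # refractory 250 ms
  pk <- find_peaks(y, thresh = thr, min_dist = min_dist)
  emg$t0 + (pk - 1) / emg$rate
}

#' Remove electrical cardiac artifacts by template subtraction
#'
#' QRS complexes are located (internally on a 5-30 Hz band-passed copy, or
#' from supplied beat times), beats are aligned in windows of +/- `half_ms`
#' around each QRS, and the median beat template - scaled per beat by least
#' squares - is subtracted. Length and rate are unchanged.
#'
#' @param emg A denoised [time_series()].
#' @param qrs_times Optional numeric vector of beat times in s; detected
#'   internally when absent.
#' @param half_ms Template half-width in ms around each QRS (default 100).
#' @param mains_hz Mains frequency notched out of the internal copy used
#'   for template estimation and per-beat fitting, making the operation
#'   insensitive to whether powerline removal ran first.
#' @return `vent_ts` with attribute `cardiac_removed` (FALSE with a warning
#'   when fewer than 3 beats were found and the input is passed through).
#' @export
remove_cardiac <- function(emg, qrs_times = NULL, half_ms = 100,
                           mains_hz = 50) {
  stopifnot(inherits(emg, "vent_ts"))
  if (is.null(qrs_times)) qrs_times <- detect_qrs(emg)
  half <- round(half_ms / 1000 * emg$rate)
  n <- length(emg$samples)
  # estimation runs on a powerline-cleaned copy (idempotent spectral mask,
  # so it is immaterial whether powerline removal already ran); the
  # subtraction itself is applied to the input
  est <- if (!is.null(mains_hz) && emg$rate > 2 * mains_hz)
    fft_mains_mask(emg$samples, emg$rate, mains_hz) else emg$samples
  raw_centers <- round((qrs_times - emg$t0) * emg$rate) + 1
  inrange <- raw_centers - half >= 1 & raw_centers + half <= n
  centers <- raw_centers[inrange]
  edge_centers <- raw_centers[!inrange]      # truncated-window beats
  if (length(centers) < 3) {
    warning("fewer than 3 detectable beats; cardiac removal skipped")
    out <- emg
    attr(out, "cardiac_removed") <- FALSE
    return(out)
  }
  wl <- 2L * half + 1L
  tau <- seq_len(wl) - (half + 1L)
  detrend <- cbind(1, tau)                     # nuisance: level + slope
  # edge-based window detrending: the line is fitted on the outer 20% of
  # the window, where the cardiac pulse has decayed, so slow baseline
  # content (respiratory pressure swings) is removed while the pulse's
  # own shape - including its linear component - is fully preserved
  edge <- abs(tau) >= 0.8 * half
  Xe <- detrend[edge, , drop = FALSE]
  hat_edge <- detrend %*% solve(crossprod(Xe), t(Xe))
  extract <- function(ctrs) vapply(ctrs, function(c0) {
    w <- est[(c0 - half):(c0 + half)]
    w - drop(hat_edge %*% w[edge])
  }, numeric(wl))
  # alignment refinement: shift each beat (+/- 25 ms) to maximize the
  # cross-correlation with the provisional median template
  template <- apply(extract(centers), 1, stats::median)
  max_shift <- round(0.025 * emg$rate)
  shifts <- -max_shift:max_shift
  for (b in seq_along(centers)) {
    cand <- centers[b] + shifts
    cand <- cand[cand - half >= 1 & cand + half <= n]
    if (length(cand) == 0) next
    cc <- vapply(cand, function(c0) {
      w <- est[(c0 - half):(c0 + half)]
      sum((w - drop(hat_edge %*% w[edge])) * template)
    }, numeric(1))
    centers[b] <- cand[which.max(cc)]
  }
  template <- apply(extract(centers), 1, stats::median)
  template <- template - mean(template)       # leave baseline untouched
  # guard against mains leaking into the template when the heart rate is
  # (near) phase-locked to the powerline: project out mains sin/cos pairs
  # (beat-locked cardiac content is broadband, the loss is small)
  proj_f <- c(50, 60)
  if (!is.null(mains_hz) && emg$rate / 2 - 1 >= mains_hz)
    proj_f <- unique(c(proj_f, seq(mains_hz, emg$rate / 2 - 1,
                                   by = mains_hz)))
  tw <- (seq_along(template) - 1) / emg$rate
  mains_basis <- do.call(cbind, lapply(proj_f, function(f)
    if (2 * f < emg$rate) cbind(sin(2 * pi * f * tw), cos(2 * pi * f * tw))))
  if (!is.null(mains_basis))
    template <- stats::lm.fit(mains_basis, template)$residuals
  if (!is.null(mains_hz) && emg$rate > 2 * mains_hz) {
    # run the template through the mains notch cascade so the subtracted
    # shape matches beats that were (or will be) powerline-filtered
    for (f0 in seq(mains_hz, emg$rate / 2 - 1, by = mains_hz)) {
      dn <- design_notch(f0, bw = 0.8, rate = emg$rate)
      template <- filtfilt_pad(dn$b, dn$a, template)
    }
  }
  dtemplate <- c(0, diff(template))           # sub-sample shift corrector
  x <- emg$samples
  if (sum(template^2) > 0) {
    for (c0 in c(centers, edge_centers)) {
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1 & idx <= n                # truncate at signal edges
      if (sum(ok) < 5) next
      # per-beat LS fit of amplitude + residual alignment (Taylor term),
      # with level and slope as nuisance regressors so slow baseline
      # content (e.g. respiratory pressure swings) is never subtracted
      B <- cbind(template[ok], dtemplate[ok], detrend[ok, ])
      fit <- stats::lm.fit(B, est[idx[ok]])
      if (anyNA(fit$coefficients[1:2])) next
      x[idx[ok]] <- x[idx[ok]] - B[, 1] * fit$coefficients[1] -
        B[, 2] * fit$coefficients[2]
    }
  }
  out <- time_series(x, emg$rate, emg$t0, emg$units)
  attr(out, "cardiac_removed") <- TRUE
  out
}

#' RMS envelope with lag compensation
#'
#' Causal moving root-mean-square over `window_ms` (edges padded by
#' reflection), then advanced by `lag_shift_ms` to cancel the filter group
#' delay, and optionally decimated to an output rate for event logic.
#'
#' @param emg Denoised [time_series()].
#' @param window_ms RMS window length in ms (default 250, the standard
#'   smoothing for respiratory sEMG).
#' @param lag_shift_ms Advance applied to the envelope in ms; the default
#'   (half the window) centres the causal RMS filter.
#' @param out_rate Output rate in Hz; the envelope is computed at native
#'   rate and band-limited-resampled (default 100 Hz to align with the
#'   pressure channels). `NULL` keeps the native rate.
#' @return A `vent_ts` of subclass `vent_envelope` with fields
#'   `window_ms` and `lag_shift_ms`.
#' @export
compute_envelope <- function(emg, window_ms = 250,
                             lag_shift_ms = window_ms / 2,
                             out_rate = 100) {
  stopifnot(inherits(emg, "vent_ts"))
  w <- round(window_ms / 1000 * emg$rate)
  if (w < 3) stop("RMS window shorter than 3 samples")
  env <- moving_rms(emg$samples, w)
  shift <- round(lag_shift_ms / 1000 * emg$rate)
  if (shift > 0) {                            # advance: shift earlier
    env <- c(env[(shift + 1):length(env)], rep(env[length(env)], shift))
  }
  out <- time_series(env, emg$rate, emg$t0, emg$units)
  if (!is.null(out_rate) && abs(out_rate - emg$rate) > 1e-9) {
    out <- resample(out, out_rate)
    out$samples[out$samples < 0] <- 0         # resampling ringing guard
  }
  out$window_ms <- window_ms
  out$lag_shift_ms <- lag_shift_ms
  class(out) <- c("vent_envelope", class(out))
  out
}

#' Assess sEMG channel quality
#'
#' Signal-to-noise ratio of the envelope inside vs outside detected
#' efforts; a channel is valid when the SNR reaches the threshold
#' (inclusive) and enough activities were detected. Invalid channels are
#' excluded from segmentation downstream.
#'
#' @param envelope A [compute_envelope()] result.
#' @param detections Effort-event data.frame from the detectors.
#' @param snr_threshold_db Minimum SNR in dB (default 6).
#' @param min_activities Minimum number of detected efforts (default 5).
#' @return List with `snr_db`, `n_activities`, `valid`.
#' @export
assess_channel <- function(envelope, detections,
                           snr_threshold_db = 6, min_activities = 5) {
  if (is.null(detections) || nrow(detections) == 0)
    return(list(snr_db = NA_real_, n_activities = 0L, valid = FALSE))
  tt <- ts_times(envelope)
  inside <- rep(FALSE, length(tt))
  for (j in seq_len(nrow(detections)))
    inside <- inside | (tt >= detections$onset[j] & tt <= detections$offset[j])
  if (!any(inside) || all(inside))
    return(list(snr_db = NA_real_, n_activities = nrow(detections),
                valid = FALSE))
  snr <- 10 * log10(mean(envelope$samples[inside]^2) /
                      mean(envelope$samples[!inside]^2))
  list(snr_db = snr, n_activities = nrow(detections),
       valid = snr >= snr_threshold_db && nrow(detections) >= min_activities)
}
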