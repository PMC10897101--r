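#' Suppress cardiogenic artifacts in esophageal pressure
#'
#' Per-beat template subtraction of the cardiogenic pressure ripple in
#' windows of +/- 150 ms around each heart beat. The template is
#' mean-removed before subtraction so the respiratory-band (< 2 Hz)
#' content of Pes is preserved.
#'
#' @param pes Pes [time_series()] in cmH2O.
#' @param beat_times Optional beat times in s (e.g. from the sEMG ECG
#'   artifact); detected internally on a 3-15 Hz band-passed copy when
#'   absent.
#' @return `vent_ts`; attribute `cardiac_removed` is `FALSE` (with a
#'   warning) when fewer than 3 beats are found.
#' @export
suppress_pes_cardiac <- function(pes, beat_times = NULL) {
  stopifnot(inherits(pes, "vent_ts"))
  if (is.null(beat_times)) {
    y <- fft_bandpass(pes$samples, pes$rate, low = 3, high = 15)
    thr <- 4 * stats::median(abs(y)) / 0.6745
    pk <- find_peaks(abs(y), thresh = thr, min_dist = round(0.4 * pes$rate))
    beat_times <- pes$t0 + (pk - 1) / pes$rate
  }
  remove_cardiac(pes, qrs_times = beat_times, half_ms = 150)
}

#' Integrate airflow to volume with drift correction
#'
#' Trapezoidal integration of flow (L/s) to volume (L); a piecewise-linear
#' drift correction pins volume to zero at each detected end-expiration
#' (sustained transition from expiratory to inspiratory flow), which
#' removes sensor-offset drift.
#'
#' @param flow Flow [time_series()] in L/s.
#' @param drift_correct Apply per-breath drift correction (default TRUE).
#' @return Volume `vent_ts` in L.
#' @export
integrate_flow <- function(flow, drift_correct = TRUE) {
  stopifnot(inherits(flow, "vent_ts"))
  dt <- 1 / flow$rate
  V <- cumtrapz(flow$samples, dt)
  if (drift_correct && length(V) > flow$rate) {
    # end-expiration: last sample of a sustained non-positive-flow run
    # followed by sustained inspiratory flow
    f <- flow$samples
    thr <- 0.02 * max(abs(f))
    insp <- f > thr
    # smooth the indicator over 150 ms to avoid jitter at the crossing
    k <- max(1L, round(0.15 * flow$rate))
    frac <- as.numeric(stats::filter(as.numeric(insp), rep(1 / k, k),
                                     sides = 1))
    frac[is.na(frac)] <- 0
    starts <- which(diff(frac >= 0.8) == 1)    # inspiration begins
    anchors <- unique(c(1L, pmax(1L, starts - k + 1L), length(V)))
    anchors <- sort(anchors)
    if (length(anchors) >= 2) {
      drift <- stats::approx(anchors, V[anchors], xout = seq_along(V),
                             rule = 2)$y
      # do not remove true end tidal volume at the final sample if the
      # recording stops mid-breath: anchor the last point to the last
      # detected end-expiration instead
      if (length(starts) >= 1) {
        last_anchor <- max(pmax(1L, starts - k + 1L))
        drift[last_anchor:length(V)] <- drift[last_anchor]
      }
      V <- V - drift
    }
  }
  time_series(V, flow$rate, flow$t0, "L")
}

#' Estimate chest-wall elastance from passive intervals
#'
#' Least-squares slope of Pes against volume over stretches with no
#' patient effort (passive insufflation), where Pes tracks the chest-wall
#' recoil `Ecw * V`. The end-expiratory baseline is the median Pes at
#' near-zero volume within the same intervals.
#'
#' @param pes Filtered Pes [time_series()] (cmH2O).
#' @param volume Volume [time_series()] (L), aligned with `pes`.
#' @param passive_intervals Two-column matrix of `[start, end]` times in s.
#' @return List of class `chest_wall_model` with `ecw` (cmH2O/L) and
#'   `pes_baseline` (cmH2O).
#' @export
estimate_ecw <- function(pes, volume, passive_intervals) {
  stopifnot(inherits(pes, "vent_ts"), inherits(volume, "vent_ts"))
  if (abs(pes$rate - volume$rate) > 1e-9)
    stop("pes and volume must share a sampling rate")
  if (is.null(passive_intervals) || nrow(passive_intervals) == 0)
    stop("no passive interval supplied; provide one or set Ecw manually")
  tt <- ts_times(pes)
  sel <- rep(FALSE, length(tt))
  for (j in seq_len(nrow(passive_intervals)))
    sel <- sel | (tt >= passive_intervals[j, 1] & tt <= passive_intervals[j, 2])
  v <- volume$samples[sel]; p <- pes$samples[sel]
  if (length(v) < 3 || stats::var(v) < 1e-12)
    stop("degenerate regression: volume has no variation in passive intervals")
  fit <- stats::lm.fit(cbind(1, v), p)
  ecw <- unname(fit$coefficients[2])
  near_zero <- abs(v) <= pmax(0.02 * max(abs(v)), 1e-9)
  baseline <- if (any(near_zero)) stats::median(p[near_zero])
              else unname(fit$coefficients[1])
  structure(list(ecw = ecw, pes_baseline = baseline),
            class = "chest_wall_model")
}

#' Derive the muscular pressure Pmus
#'
#' `Pmus(t) = Ecw * V(t) - (Pes(t) - baseline)`: esophageal pressure
#' corrected for the volume-dependent elastic recoil of the chest wall,
#' sign-flipped so that inspiratory effort is a positive deflection.
#'
#' @param pes_filtered Cardiac-suppressed Pes [time_series()].
#' @param volume Volume [time_series()] aligned with `pes_filtered`.
#' @param cw A [estimate_ecw()] chest-wall model.
#' @return Pmus `vent_ts` (cmH2O), positive during inspiratory effort.
#' @export
derive_pmus <- function(pes_filtered, volume, cw) {
  stopifnot(inherits(cw, "chest_wall_model"))
  if (abs(pes_filtered$rate - volume$rate) > 1e-9 ||
      length(pes_filtered) != length(volume))
    stop("pes and volume series are misaligned")
  pmus <- cw$ecw * volume$samples -
    (pes_filtered$samples - cw$pes_baseline)
  time_series(pmus, pes_filtered$rate, pes_filtered$t0, "cmH2O")
}

#' Effort end by the 70 percent rule on Pmus
#'
#' Locates the peak of Pmus in `[onset, search_end]` and returns the first
#' time after the peak at which Pmus falls below `fraction` of the peak;
#' `search_end` when it never does.
#'
#' @param pmus Pmus [time_series()].
#' @param onset Effort onset time in s.
#' @param search_end End of the search window in s (e.g. next onset).
#' @param fraction Offset fraction of the peak (default 0.7).
#' @return End time in s; attribute `degenerate` is TRUE when the peak is
#'   non-positive.
#' @export
effort_end_pmus <- function(pmus, onset, search_end, fraction = 0.7) {
  stopifnot(inherits(pmus, "vent_ts"), onset < search_end)
  i0 <- ts_index(pmus, onset); i1 <- ts_index(pmus, search_end)
  seg <- pmus$samples[i0:i1]
  ip <- which.max(seg)
  peak <- seg[ip]
  out_attr <- peak <= 0
  below <- which(seg[seq(ip, length(seg))] < fraction * peak)
  t_end <- if (length(below) == 0) search_end else
    pmus$t0 + (i0 - 1 + ip - 1 + below[1] - 1) / pmus$rate
  structure(min(t_end, search_end), degenerate = out_attr)
}
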