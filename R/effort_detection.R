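#' Effort event table constructor
#'
#' @param onset,offset,peak_time,peak_amp Numeric vectors (s, s, s, uV).
#' @param source Channel of origin (`emg_di`, `emg_para`, `fused`,
#'   `pes_reference`).
#' @param algorithm Detector (`triangle`, `adaptive`, `manual`).
#' @return data.frame of class `vent_efforts`, sorted by onset.
#' @export
effort_events <- function(onset = numeric(0), offset = numeric(0),
                          peak_time = NA_real_, peak_amp = NA_real_,
                          source = "fused", algorithm = "manual") {
  n <- length(onset)
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   peak_time = rep_len(peak_time, n),
                   peak_amp = rep_len(peak_amp, n),
                   source = rep_len(source, n),
                   algorithm = rep_len(algorithm, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$offset < df$onset)) stop("offset before onset")
    df <- df[order(df$onset), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("vent_efforts", "data.frame")
  df
}

#' Detector parameters
#'
#' Defaults for both sEMG burst detectors. The 40 % relative amplitude
#' threshold of the triangle algorithm and the 70 % offset fraction are
#' the field-standard values; window, refractory and adaptive constants
#' are declared defaults, all overridable.
#'
#' @param relative_amp_threshold Triangle: peaks must reach this fraction
#'   of the window's baseline-to-maximum range (default 0.4).
#' @param refractory_ms Triangle: events closer than this are merged.
#' @param analysis_window_s Triangle: analysis window length in s.
#' @param k_sigma Adaptive: threshold at `mu + k_sigma * sigma` of the
#'   running noise statistics.
#' @param sustain_ms Adaptive: threshold must be exceeded this long.
#' @param noise_time_constant_s Adaptive: exponential forgetting time
#'   constant of the noise statistics.
#' @param threshold_floor Minimum envelope excursion (uV) treated as
#'   activity; flat envelopes yield no events.
#' @param offset_fraction Effort end when the baseline-referenced envelope
#'   falls below this fraction of its peak (default 0.7).
#' @return List of class `detector_params`.
#' @export
detector_params <- function(relative_amp_threshold = 0.4,
                            refractory_ms = 300,
                            analysis_window_s = 30,
                            k_sigma = 3,
                            sustain_ms = 60,
                            noise_time_constant_s = 2,
                            threshold_floor = 0.5,
                            offset_fraction = 0.7) {
  stopifnot(relative_amp_threshold > 0, relative_amp_threshold < 1,
            offset_fraction > 0, offset_fraction < 1,
            refractory_ms > 0, analysis_window_s > 0, sustain_ms > 0,
            noise_time_constant_s > 0, k_sigma > 0)
  structure(list(relative_amp_threshold = relative_amp_threshold,
                 refractory_ms = refractory_ms,
                 analysis_window_s = analysis_window_s,
                 k_sigma = k_sigma, sustain_ms = sustain_ms,
                 noise_time_constant_s = noise_time_constant_s,
                 threshold_floor = threshold_floor,
                 offset_fraction = offset_fraction),
            class = "detector_params")
}

#' Effort end by the 70 percent rule on the envelope
#'
#' Baseline-referenced variant of the classic offset rule: with the local
#' pre-onset envelope level as baseline, the effort ends at the first time
#' after the envelope peak where `env - baseline` drops below
#' `offset_fraction * (peak - baseline)`; the search bound is returned if
#' it never does.
#'
#' @param env A [compute_envelope()] result (any `vent_ts` works).
#' @param onset Effort onset in s.
#' @param bound Search bound in s (next onset or end of signal).
#' @param offset_fraction Fraction of the peak (default 0.7).
#' @return End time in s.
#' @export
effort_end_envelope <- function(env, onset, bound, offset_fraction = 0.7) {
  stopifnot(onset < bound)
  i0 <- ts_index(env, onset); i1 <- ts_index(env, bound)
  ib <- ts_index(env, onset - 0.25)
  baseline <- stats::median(env$samples[ib:i0])
  seg <- env$samples[i0:i1]
  ip <- which.max(seg)
  peak <- seg[ip]
  if (peak <= baseline) return(bound)
  below <- which(seg[seq(ip, length(seg))] - baseline <
                   offset_fraction * (peak - baseline))
  if (length(below) == 0) return(bound)
  min(env$t0 + (i0 - 1 + ip - 1 + below[1] - 1) / env$rate, bound)
}

#' Triangle algorithm: robust onset detection in the sEMG envelope
#'
#' Per analysis window, candidate peaks are local envelope maxima reaching
#' at least 40 % (default) of the window's baseline-to-maximum amplitude
#' range (baseline = 5th percentile). For each peak the onset is placed at
#' the elbow of the rising edge: the point between the preceding local
#' minimum and the peak with maximum perpendicular distance to the chord
#' joining them (computed on axis-normalized coordinates, which makes the
#' placement invariant to envelope scaling). Events closer than the
#' refractory period are merged (earlier onset, higher peak); offsets
#' follow [effort_end_envelope()].
#'
#' @param env A [compute_envelope()] result.
#' @param params A [detector_params()].
#' @param source Label recorded in the `source` column.
#' @return [effort_events()] table.
#' @export
detect_triangle <- function(env, params = detector_params(),
                            source = "emg_di") {
  x <- env$samples
  n <- length(x)
  rate <- env$rate
  wlen <- max(3L, round(params$analysis_window_s * rate))
  refr <- round(params$refractory_ms / 1000 * rate)
  ev <- list()
  w_starts <- seq(1L, n, by = wlen)
  # fold a trailing fragment (< half a window) into the previous window
  if (length(w_starts) > 1 && n - w_starts[length(w_starts)] + 1L < wlen / 2)
    w_starts <- w_starts[-length(w_starts)]
  for (w0 in w_starts) {
    w1 <- if (w0 == w_starts[length(w_starts)]) n else min(n, w0 + wlen - 1L)
    seg <- x[w0:w1]
    b <- stats::quantile(seg, 0.05, names = FALSE)
    M <- max(seg)
    if (M - b < params$threshold_floor) next
    thr <- b + params$relative_amp_threshold * (M - b)
    pks <- find_peaks(seg, thresh = thr, min_dist = max(1L, refr))
    prev_peak <- 1L
    for (tp in pks) {
      tm <- prev_peak - 1L + which.min(seg[prev_peak:tp])
      # a genuine burst must rise from a real trough: if the envelope never
      # fell below the offset fraction of this peak since the previous one,
      # the "peak" is a ripple on ongoing activity
      if (prev_peak > 1L &&
          seg[tm] - b >= params$offset_fraction * (seg[tp] - b)) {
        prev_peak <- max(prev_peak, tp)
        next
      }
      if (tp - tm >= 2L) {
        xs <- seq(tm, tp)
        xn <- (xs - tm) / (tp - tm)
        dy <- seg[tp] - seg[tm]
        yn <- if (dy > 0) (seg[xs] - seg[tm]) / dy else rep(0, length(xs))
        onset_i <- xs[which.max(xn - yn)]     # elbow: farthest below chord
      } else onset_i <- tm
      ev[[length(ev) + 1L]] <- c(onset = w0 - 1L + onset_i,
                                 peak = w0 - 1L + tp)
      prev_peak <- tp
    }
  }
  if (length(ev) == 0)
    return(effort_events(source = source, algorithm = "triangle")[0, ])
  em <- do.call(rbind, ev)
  em <- em[order(em[, "onset"]), , drop = FALSE]
  # refractory merge across window joints: keep earlier onset, higher peak
  keep <- list(em[1, ])
  for (i in seq_len(nrow(em))[-1]) {
    last <- keep[[length(keep)]]
    if (em[i, "onset"] - last["peak"] <= refr) {
      if (x[em[i, "peak"]] > x[last["peak"]])
        keep[[length(keep)]]["peak"] <- em[i, "peak"]
    } else keep[[length(keep) + 1L]] <- em[i, ]
  }
  em <- do.call(rbind, keep)
  onset_t <- env$t0 + (em[, "onset"] - 1) / rate
  bounds <- c(onset_t[-1], env$t0 + (n - 1) / rate)
  offs <- peak_t <- peak_a <- numeric(nrow(em))
  for (i in seq_len(nrow(em))) {
    offs[i] <- effort_end_envelope(env, onset_t[i], bounds[i],
                                   params$offset_fraction)
    peak_t[i] <- env$t0 + (em[i, "peak"] - 1) / rate
    peak_a[i] <- x[em[i, "peak"]]
  }
  effort_events(onset_t, offs, peak_t, peak_a, source, "triangle")
}

#' Adaptive thresholding algorithm: sensitive onset detection
#'
#' Running noise statistics `mu(t)`, `sigma(t)` are updated by exponential
#' forgetting while the envelope is at or below the current threshold
#' `T = max(mu + k_sigma * sigma, mu + threshold_floor)` and frozen during
#' activity. An effort starts at the first sample of a run exceeding the
#' threshold for at least `sustain_ms`; it ends by the 70 % offset rule
#' referenced to the frozen `mu`, after which adaptation resumes. The
#' quickly tracking threshold makes the detector sensitive to small
#' activities that the triangle algorithm's 40 % amplitude rule discards.
#' After an event the detector re-arms only once the envelope has returned
#' below the threshold, so one burst yields one event.
#'
#' @inheritParams detect_triangle
#' @return [effort_events()] table.
#' @export
detect_adaptive <- function(env, params = detector_params(),
                            source = "emg_di") {
  x <- env$samples
  n <- length(x)
  rate <- env$rate
  alpha <- 1 / (params$noise_time_constant_s * rate)
  sustain <- max(1L, round(params$sustain_ms / 1000 * rate))
  init <- x[seq_len(min(n, round(rate)))]
  mu <- stats::median(init)
  s2 <- stats::mad(init)^2
  run <- 0L
  state <- "noise"
  onset_i <- peak_i <- 0L
  base <- mu
  ev <- list()
  i <- 1L
  while (i <= n) {
    thr <- mu + max(params$k_sigma * sqrt(s2), params$threshold_floor)
    if (state == "noise") {
      if (x[i] > thr) {
        run <- run + 1L
        if (run >= sustain) {
          state <- "active"
          onset_i <- i - run + 1L
          peak_i <- onset_i - 1L + which.max(x[onset_i:i])
          base <- mu
          run <- 0L
        }
      } else {
        run <- 0L
        mu <- mu + alpha * (x[i] - mu)
        s2 <- s2 + alpha * ((x[i] - mu)^2 - s2)
      }
    } else if (state == "active") {
      if (x[i] > x[peak_i]) peak_i <- i
      done <- i > peak_i &&
        (x[i] - base) < params$offset_fraction * (x[peak_i] - base)
      if (done || i == n) {
        ev[[length(ev) + 1L]] <- c(onset = onset_i, off = i, peak = peak_i)
        state <- "rearm"     # wait for return below threshold
      }
    } else {                 # rearm: no detection until below threshold
      if (x[i] <= thr) {
        state <- "noise"
        mu <- mu + alpha * (x[i] - mu)
        s2 <- s2 + alpha * ((x[i] - mu)^2 - s2)
      }
    }
    i <- i + 1L
  }
  if (length(ev) == 0)
    return(effort_events(source = source, algorithm = "adaptive")[0, ])
  em <- do.call(rbind, ev)
  effort_events(env$t0 + (em[, "onset"] - 1) / rate,
                env$t0 + (em[, "off"] - 1) / rate,
                env$t0 + (em[, "peak"] - 1) / rate,
                x[em[, "peak"]], source, "adaptive")
}

#' Fuse effort detections from two sEMG channels
#'
#' Events whose intervals overlap (transitively) are merged into one fused
#' event taking the earlier of the detected onsets as the start of
#' electrical activity and the latest offset as its end; events present in
#' only one channel are kept as-is.
#'
#' @param a,b [effort_events()] tables from two valid channels of the same
#'   recording (either may be empty).
#' @return Fused [effort_events()] table sorted by onset.
#' @export
fuse_channels <- function(a, b) {
  if (is.null(a) || nrow(a) == 0) return(b)
  if (is.null(b) || nrow(b) == 0) return(a)
  all_ev <- rbind(as.data.frame(a), as.data.frame(b))
  all_ev <- all_ev[order(all_ev$onset), , drop = FALSE]
  out <- all_ev[1, , drop = FALSE]
  merged <- 1L
  for (i in seq_len(nrow(all_ev))[-1]) {
    j <- nrow(out)
    if (all_ev$onset[i] < out$offset[j]) {     # positive-duration overlap
      out$offset[j] <- max(out$offset[j], all_ev$offset[i])
      if (!is.na(all_ev$peak_amp[i]) &&
          (is.na(out$peak_amp[j]) || all_ev$peak_amp[i] > out$peak_amp[j])) {
        out$peak_amp[j] <- all_ev$peak_amp[i]
        out$peak_time[j] <- all_ev$peak_time[i]
      }
      out$source[j] <- "fused"
      merged <- merged + 1L
    } else {
      out <- rbind(out, all_ev[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  class(out) <- c("vent_efforts", "data.frame")
  out
}
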