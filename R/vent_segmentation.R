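#' Segment ventilator insufflations from airway pressure
#'
#' A mechanical breath starts with the first sample of the positive ramp in
#' Paw and ends with the first sample of the falling edge. Operationally:
#' PEEP is estimated as the mode of the smoothed Paw over the expiratory
#' majority of samples; a pressurization is flagged where smoothed Paw
#' exceeds `PEEP + rise_delta`; its start is backtracked to the ramp foot
#' (last sample with non-positive smoothed derivative) and its end is the
#' first sample where the smoothed derivative drops below `fall_slope`
#' sustained for 30 ms. Events shorter than `min_support_ms` are discarded.
#' On clean waveforms this reduces exactly to the two landmark definitions.
#'
#' @param paw Airway-pressure [time_series()] (cmH2O, typically 100 Hz).
#' @param rise_delta Hysteresis above PEEP in cmH2O (default 1).
#' @param fall_slope Cycling-off slope threshold in cmH2O/s (default -20).
#' @param min_support_ms Minimum insufflation length in ms (default 200).
#' @return data.frame of class `vent_supports` with columns `t_start`,
#'   `t_end`, `peep`, `peak_paw`; empty (with a warning) when no cycle is
#'   found.
#' @export
segment_supports <- function(paw, rise_delta = 1.0, fall_slope = -20,
                             min_support_ms = 200) {
  stopifnot(inherits(paw, "vent_ts"))
  rate <- paw$rate
  n <- length(paw$samples)
  empty <- function() {
    df <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     peep = numeric(0), peak_paw = numeric(0))
    class(df) <- c("vent_supports", "data.frame")
    df
  }
  if (n < rate / 2) { warning("no ventilator cycles found"); return(empty()) }
  # light smoothing (50 ms) for PEEP/derivative logic
  k <- max(1L, round(0.05 * rate))
  sm <- stats::filter(paw$samples, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- paw$samples[is.na(sm)]
  # PEEP: mode of the lower (expiratory) half of the smoothed pressure
  lower <- sm[sm <= stats::quantile(sm, 0.6, names = FALSE)]
  dens <- stats::density(lower, n = 512)
  peep <- dens$x[which.max(dens$y)]
  above <- sm > peep + rise_delta
  rises <- which(diff(c(FALSE, above)) == 1)
  if (length(rises) == 0) { warning("no ventilator cycles found"); return(empty()) }
  deriv <- c(0, diff(sm)) * rate
  sustain <- max(1L, round(0.03 * rate))
  res <- list()
  for (r in rises) {
    # locate the ramp foot by extrapolating the initial ramp slope back
    # to the PEEP level (robust to noise; exact on clean ramps/steps)
    r3 <- r
    while (r3 < n && sm[r3] < peep + 3 * rise_delta &&
           (r3 - r) < round(0.3 * rate)) r3 <- r3 + 1L
    slope <- if (r3 > r) (sm[r3] - sm[r]) / (r3 - r) else Inf
    t_start <- if (is.finite(slope) && slope > 1e-9)
      max(1L, round(r - (sm[r] - peep) / slope)) else r
    # find cycling off: first sample after pressurization with derivative
    # below fall_slope sustained 30 ms
    j <- r
    t_end <- NA_integer_
    while (j <= n - sustain) {
      if (all(deriv[j:(j + sustain - 1)] < fall_slope)) { t_end <- j; break }
      j <- j + 1L
    }
    if (is.na(t_end)) next
    res[[length(res) + 1L]] <- c(t_start, t_end)
  }
  if (length(res) == 0) { warning("no ventilator cycles found"); return(empty()) }
  em <- unique(do.call(rbind, res))
  # drop duplicates from multiple rise crossings within one breath
  keep <- c(TRUE, diff(em[, 2]) > 0 & em[-1, 1] > em[-nrow(em), 2])
  em <- em[keep, , drop = FALSE]
  dur_ok <- (em[, 2] - em[, 1]) / rate * 1000 >= min_support_ms
  em <- em[dur_ok, , drop = FALSE]
  if (nrow(em) == 0) { warning("no ventilator cycles found"); return(empty()) }
  df <- data.frame(
    t_start = paw$t0 + (em[, 1] - 1) / rate,
    t_end = paw$t0 + (em[, 2] - 1) / rate,
    peep = peep,
    peak_paw = vapply(seq_len(nrow(em)), function(i)
      max(paw$samples[em[i, 1]:em[i, 2]]), numeric(1)))
  rownames(df) <- NULL
  class(df) <- c("vent_supports", "data.frame")
  df
}
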