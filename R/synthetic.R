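#' Scenario configuration for the synthetic ventilated-patient generator
#'
#' Describes a pressure-support ventilation scenario with a scripted mix of
#' patient-ventilator interaction classes. Defaults are a typical ICU
#' pressure-support setting with clearly visible inspiratory sEMG bursts
#' (about 20 dB in-burst power ratio over the noise floor).
#'
#' @param duration Recording length in s.
#' @param respiratory_rate Breath cycles per minute (one scripted event
#'   constellation per cycle).
#' @param effort_amplitude Named numeric, peak burst amplitude in uV for
#'   channels `emg_di` and `emg_para`.
#' @param noise_floor Baseline sEMG noise RMS in uV.
#' @param ecg_rate Heart rate in bpm for the ECG artifact train.
#' @param ecg_amplitude QRS peak amplitude in uV on the sEMG channels.
#' @param powerline_amplitude 50 Hz mains interference amplitude in uV.
#' @param pes_effort_amplitude Peak inspiratory Pes deflection in cmH2O.
#' @param chest_wall_elastance Ecw in cmH2O/L (chest-wall recoil in Pes).
#' @param support_pressure Pressure support above PEEP in cmH2O.
#' @param peep Positive end-expiratory pressure in cmH2O.
#' @param event_mix Named probabilities over the six interaction classes
#'   `synchronous`, `delayed`, `auto_trigger`, `ineffective`,
#'   `double_trigger`, `double_effort`; must sum to 1. Events are scripted:
#'   per-class counts are the rounded shares of the breath count.
#' @param trigger_delay_range Range (s) for delayed-trigger delays; must lie
#'   within (0.25, 0.6]. Synchronous delays are drawn from [0.05, 0.25] s.
#' @param paw_noise_sd,pes_noise_sd Additive measurement noise SD (cmH2O).
#' @param weak_fraction Fraction of efforts scripted as low-amplitude
#'   (sEMG burst scaled by `weak_scale`); the ground-truth column
#'   `amp_scale` records the per-effort scaling.
#' @param weak_scale Amplitude scale of low-amplitude efforts (default
#'   0.3, i.e. at most 35 % of the maximal burst amplitude).
#' @param seed Integer RNG seed; same config + seed gives identical output.
#' @return A validated list of class `vent_scenario`.
#' @export
scenario_config <- function(duration = 60,
                            respiratory_rate = 15,
                            effort_amplitude = c(emg_di = 16, emg_para = 16),
                            noise_floor = 1,
                            ecg_rate = 80,
                            ecg_amplitude = 60,
                            powerline_amplitude = 20,
                            pes_effort_amplitude = 8,
                            chest_wall_elastance = 5,
                            support_pressure = 8,
                            peep = 5,
                            event_mix = c(synchronous = 1, delayed = 0,
                                          auto_trigger = 0, ineffective = 0,
                                          double_trigger = 0, double_effort = 0),
                            trigger_delay_range = c(0.3, 0.55),
                            paw_noise_sd = 0.05,
                            pes_noise_sd = 0.05,
                            weak_fraction = 0,
                            weak_scale = 0.3,
                            seed = 1L) {
  classes <- c("synchronous", "delayed", "auto_trigger", "ineffective",
               "double_trigger", "double_effort")
  mix <- rep(0, 6); names(mix) <- classes
  if (is.null(names(event_mix)) || !all(names(event_mix) %in% classes))
    stop("event_mix must be named with interaction classes")
  mix[names(event_mix)] <- event_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("event_mix probabilities must sum to 1")
  if (any(mix < 0)) stop("event_mix probabilities must be >= 0")
  amp <- c(emg_di = NA_real_, emg_para = NA_real_)
  if (length(effort_amplitude) == 1 && is.null(names(effort_amplitude)))
    effort_amplitude <- c(emg_di = effort_amplitude, emg_para = effort_amplitude)
  amp[names(effort_amplitude)] <- effort_amplitude
  if (anyNA(amp)) stop("effort_amplitude must name emg_di and emg_para")
  for (v in list(duration, respiratory_rate, noise_floor, ecg_rate,
                 ecg_amplitude, powerline_amplitude, pes_effort_amplitude,
                 chest_wall_elastance, support_pressure, peep))
    if (!is.numeric(v) || length(v) != 1 || v < 0) stop("amplitudes/rates must be >= 0")
  if (amp[1] < 0 || amp[2] < 0) stop("effort_amplitude must be >= 0")
  if (trigger_delay_range[1] <= 0.25 || trigger_delay_range[2] > 0.6 ||
      diff(trigger_delay_range) < 0)
    stop("trigger_delay_range must lie within (0.25, 0.6]")
  structure(list(
    duration = duration, respiratory_rate = respiratory_rate,
    effort_amplitude = amp, noise_floor = noise_floor, ecg_rate = ecg_rate,
    ecg_amplitude = ecg_amplitude, powerline_amplitude = powerline_amplitude,
    pes_effort_amplitude = pes_effort_amplitude,
    chest_wall_elastance = chest_wall_elastance,
    support_pressure = support_pressure, peep = peep, event_mix = mix,
    trigger_delay_range = trigger_delay_range,
    paw_noise_sd = paw_noise_sd, pes_noise_sd = pes_noise_sd,
    weak_fraction = weak_fraction, weak_scale = weak_scale,
    seed = as.integer(seed)), class = "vent_scenario")
}

# band-limited (low..high Hz) unit-RMS Gaussian noise
bandlimited_noise <- function(n, rate, low, high) {
  x <- fft_bandpass(stats::rnorm(n), rate, low = low, high = high)
  x / stats::sd(x)
}

# biphasic QRS-like pulse, ~80 ms wide, peak 1
qrs_template <- function(rate, width_s = 0.08) {
  t <- seq(-width_s / 2, width_s / 2, by = 1 / rate)
  w <- width_s / 2
  pulse <- sin(2 * pi * t / width_s) * exp(-(t / (0.35 * w))^2)
  pulse / max(abs(pulse))
}

# raised-cosine activation over [on, off] evaluated on time grid tt
activation_on <- function(tt, on, off) {
  a <- numeric(length(tt))
  i <- tt >= on & tt <= off
  a[i] <- 0.5 * (1 - cos(2 * pi * (tt[i] - on) / (off - on)))
  a
}

#' Generate a coupled synthetic recording with ground truth
#'
#' Produces a [recording()] with channels `paw`, `flow`, `pes` (100 Hz) and
#' `emg_di`, `emg_para` (1000 Hz), plus the scripted ground-truth event
#' table. sEMG channels are burst-modulated band-limited (20-250 Hz) noise
#' on a Gaussian noise floor with ECG and 50 Hz powerline contamination.
#' Pes carries the negative inspiratory deflection, chest-wall recoil
#' `Ecw * V(t)` and a cardiogenic ripple. Paw is a trapezoidal
#' pressure-support waveform above PEEP; flow follows a single-compartment
#' lung model so that volume returns to (near) zero at end-expiration.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `recording` (a `vent_recording`) and
#'   `truth` (data.frame: `effort_on`, `effort_off`, `support_on`,
#'   `support_off`, `label`, `delay`; `NA` marks an absent interval).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "vent_scenario"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  period <- 60 / config$respiratory_rate
  n_breaths <- max(0L, floor((config$duration - 0.5) / period))
  classes <- names(config$event_mix)

  # scripted per-class counts: rounded shares, remainder by largest fraction
  share <- config$event_mix * n_breaths
  cnt <- floor(share)
  rem <- n_breaths - sum(cnt)
  if (rem > 0) {
    extra <- order(share - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  labels <- sample(rep(classes, times = cnt))

  # script the event constellations, one per breath cycle
  truth <- list()
  for (k in seq_len(n_breaths)) {
    tc <- (k - 1) * period + 0.4
    lab <- labels[k]
    rows <- switch(lab,
      synchronous = {
        d <- stats::runif(1, 0.05, 0.25)
        data.frame(effort_on = tc, effort_off = tc + 1.0,
                   support_on = tc + d, support_off = tc + d + 1.0,
                   label = "synchronous", delay = d)
      },
      delayed = {
        d <- stats::runif(1, config$trigger_delay_range[1],
                          config$trigger_delay_range[2])
        data.frame(effort_on = tc, effort_off = tc + 1.0,
                   support_on = tc + d, support_off = tc + d + 1.0,
                   label = "delayed", delay = d)
      },
      auto_trigger = data.frame(effort_on = NA, effort_off = NA,
                                support_on = tc + 0.2, support_off = tc + 1.2,
                                label = "auto_trigger", delay = NA),
      ineffective = data.frame(effort_on = tc, effort_off = tc + 1.0,
                               support_on = NA, support_off = NA,
                               label = "ineffective", delay = NA),
      double_trigger = {
        d <- stats::runif(1, 0.05, 0.25)
        rbind(
          data.frame(effort_on = tc, effort_off = tc + 1.9,
                     support_on = tc + d, support_off = tc + d + 0.7,
                     label = "synchronous", delay = d),
          data.frame(effort_on = NA, effort_off = NA,
                     support_on = tc + d + 0.95, support_off = tc + d + 1.6,
                     label = "double_trigger", delay = NA))
      },
      double_effort = {
        d <- stats::runif(1, 0.05, 0.25)
        rbind(
          data.frame(effort_on = tc, effort_off = tc + 0.9,
                     support_on = tc + d, support_off = tc + d + 1.6,
                     label = "synchronous", delay = d),
          data.frame(effort_on = tc + 1.05, effort_off = tc + 1.75,
                     support_on = NA, support_off = NA,
                     label = "double_effort", delay = NA))
      })
    truth[[length(truth) + 1L]] <- rows
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(effort_on = numeric(0), effort_off = numeric(0),
               support_on = numeric(0), support_off = numeric(0),
               label = character(0), delay = numeric(0))
  rownames(truth) <- NULL

  # script low-amplitude efforts
  truth$amp_scale <- ifelse(is.na(truth$effort_on), NA_real_, 1)
  if (config$weak_fraction > 0) {
    eidx <- which(!is.na(truth$effort_on))
    nweak <- floor(config$weak_fraction * length(eidx))
    if (nweak > 0)
      truth$amp_scale[sample(eidx, nweak)] <- config$weak_scale
  }

  efforts <- truth[!is.na(truth$effort_on),
                   c("effort_on", "effort_off", "amp_scale")]
  supports <- truth[!is.na(truth$support_on), c("support_on", "support_off")]

  rate_p <- 100; rate_e <- 1000
  n_p <- round(config$duration * rate_p)
  n_e <- round(config$duration * rate_e)
  tt_p <- (seq_len(n_p) - 1) / rate_p
  tt_e <- (seq_len(n_e) - 1) / rate_e

  # ---- ventilator pressure: trapezoid above PEEP ----------------------
  rise <- 0.15; fall <- 0.10
  paw_drive <- numeric(n_p)                      # above PEEP, noise-free
  for (j in seq_len(nrow(supports))) {
    s0 <- supports$support_on[j]; s1 <- supports$support_off[j]
    seg <- tt_p >= s0 & tt_p < s1
    paw_drive[seg] <- config$support_pressure *
      pmin((tt_p[seg] - s0) / rise, 1)
    tail_ <- tt_p >= s1 & tt_p < s1 + fall
    paw_drive[tail_] <- config$support_pressure * (1 - (tt_p[tail_] - s1) / fall)
  }

  # ---- patient pressure drive and lung model --------------------------
  act_p <- numeric(n_p)
  for (j in seq_len(nrow(efforts)))
    act_p <- act_p + activation_on(tt_p, efforts$effort_on[j],
                                   efforts$effort_off[j])
  pmus_drive <- config$pes_effort_amplitude * act_p

  Rrs <- 10; Ers <- 25                           # cmH2O/(L/s), cmH2O/L
  V <- numeric(n_p); flow <- numeric(n_p)
  dt <- 1 / rate_p
  for (i in seq_len(n_p - 1)) {
    flow[i] <- (paw_drive[i] + pmus_drive[i] - Ers * V[i]) / Rrs
    V[i + 1] <- V[i] + flow[i] * dt
  }
  flow[n_p] <- (paw_drive[n_p] + pmus_drive[n_p] - Ers * V[n_p]) / Rrs

  # ---- ECG beat train -------------------------------------------------
  beat_period <- 60 / config$ecg_rate
  beats <- seq(0.3, config$duration, by = beat_period)
  beats <- beats + stats::rnorm(length(beats), 0, 0.005)
  beats <- beats[beats > 0.1 & beats < config$duration - 0.1]

  place_train <- function(n, rate, times, template, amps) {
    y <- numeric(n)
    half <- (length(template) - 1) %/% 2
    for (j in seq_along(times)) {
      c0 <- round(times[j] * rate) + 1
      lo <- c0 - half; hi <- c0 + half
      if (lo < 1 || hi > n) next
      y[lo:hi] <- y[lo:hi] + amps[j] * template
    }
    y
  }

  # ---- sEMG channels --------------------------------------------------
  qrs_e <- qrs_template(rate_e)
  ecg_amps <- config$ecg_amplitude * stats::runif(length(beats), 0.9, 1.1)
  emg <- list()
  for (ch in c("emg_di", "emg_para")) {
    x <- config$noise_floor * bandlimited_noise(n_e, rate_e, 20, 250)
    for (j in seq_len(nrow(efforts))) {
      on <- efforts$effort_on[j]; off <- efforts$effort_off[j]
      a <- activation_on(tt_e, on, off)
      i <- which(a > 0)
      if (length(i) > 10) {
        carrier <- bandlimited_noise(length(i), rate_e, 20, 250)
        x[i] <- x[i] + config$effort_amplitude[[ch]] *
          efforts$amp_scale[j] * a[i] * carrier
      }
    }
    x <- x + place_train(n_e, rate_e, beats, qrs_e, ecg_amps)
    x <- x + config$powerline_amplitude * sin(2 * pi * 50 * tt_e)
    emg[[ch]] <- time_series(x, rate_e, 0, "uV")
  }

  # ---- pressures ------------------------------------------------------
  pes_baseline <- 3
  ripple_amp <- if (config$ecg_amplitude > 0) 1.0 else 0
  ripple_tpl <- qrs_template(rate_p, width_s = 0.24)
  ripple <- place_train(n_p, rate_p, beats, ripple_tpl,
                        rep(ripple_amp, length(beats)))
  pes <- pes_baseline + config$chest_wall_elastance * V - pmus_drive +
    ripple + stats::rnorm(n_p, 0, config$pes_noise_sd)
  paw <- config$peep + paw_drive + stats::rnorm(n_p, 0, config$paw_noise_sd)

  rec <- recording(
    c(list(paw = time_series(paw, rate_p, 0, "cmH2O"),
           flow = time_series(flow, rate_p, 0, "L/s"),
           pes = time_series(pes, rate_p, 0, "cmH2O")),
      emg),
    meta = list(generator = "ventsync-synthetic", seed = config$seed,
                ecg_beats = beats, pes_baseline = pes_baseline,
                ecw = config$chest_wall_elastance))
  list(recording = rec, truth = truth)
}

#' Intervals free of patient effort
#'
#' Complement of the ground-truth effort intervals (with a guard margin),
#' used to mark passive stretches for chest-wall elastance estimation.
#'
#' @param truth Ground-truth table from [generate_recording()].
#' @param duration Recording duration in s.
#' @param margin Guard margin in s around each effort.
#' @return Two-column matrix of `[start, end]` intervals.
#' @export
passive_intervals <- function(truth, duration, margin = 0.2) {
  eff <- truth[!is.na(truth$effort_on), , drop = FALSE]
  if (nrow(eff) == 0) return(matrix(c(0, duration), ncol = 2))
  on <- sort(eff$effort_on) - margin
  off <- sort(eff$effort_off) + margin
  starts <- c(0, off)
  ends <- c(on, duration)
  keep <- ends - starts > 0.05
  cbind(starts[keep], ends[keep])
}

#' Signal-to-noise ratio of the generated sEMG channels
#'
#' Denoises each sEMG channel (powerline + cardiac removal) and reports
#' `10 log10(mean power inside effort intervals / mean power outside)` in
#' dB, per channel.
#'
#' @param recgt List as returned by [generate_recording()], or a recording
#'   plus `truth` given separately.
#' @param truth Ground-truth table (if `recgt` is a `vent_recording`).
#' @return Named numeric vector of dB values per sEMG channel.
#' @export
snr_of <- function(recgt, truth = NULL) {
  if (inherits(recgt, "vent_recording")) {
    rec <- recgt
  } else {
    rec <- recgt$recording
    if (is.null(truth)) truth <- recgt$truth
  }
  eff <- truth[!is.na(truth$effort_on), , drop = FALSE]
  if (nrow(eff) == 0)
    stop("SNR undefined: ground truth contains no patient efforts")
  beats <- rec$meta$ecg_beats
  out <- c()
  for (ch in intersect(c("emg_di", "emg_para"), names(rec$channels))) {
    x <- rec$channels[[ch]]
    x <- remove_powerline(x, 50)
    x <- remove_cardiac(x, qrs_times = beats)
    tt <- ts_times(x)
    inside <- rep(FALSE, length(tt))
    for (j in seq_len(nrow(eff)))
      inside <- inside | (tt >= eff$effort_on[j] & tt <= eff$effort_off[j])
    out[ch] <- 10 * log10(mean(x$samples[inside]^2) /
                            mean(x$samples[!inside]^2))
  }
  out
}
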