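#' Pipeline configuration
#'
#' Nested configuration for an end-to-end run. Every stage default is the
#' module default; any entry can be overridden.
#'
#' @param algorithm sEMG detector: `"triangle"`, `"adaptive"` or `"both"`
#'   (both are run and reported separately).
#' @param mains_hz Powerline frequency (50 or 60).
#' @param rms_window_ms,lag_shift_ms Envelope parameters, see
#'   [compute_envelope()].
#' @param cardiac_removal `"template"` or `"off"`.
#' @param snr_threshold_db,min_activities Channel validity gates, see
#'   [assess_channel()].
#' @param detector A [detector_params()] list.
#' @param rise_delta,fall_slope,min_support_ms Support segmentation, see
#'   [segment_supports()].
#' @param sync_threshold_s Synchronous/delayed boundary (s).
#' @return List of class `vent_config`.
#' @export
pipeline_config <- function(algorithm = c("both", "triangle", "adaptive"),
                            mains_hz = 50,
                            rms_window_ms = 250,
                            lag_shift_ms = rms_window_ms / 2,
                            cardiac_removal = c("template", "off"),
                            snr_threshold_db = 6,
                            min_activities = 5,
                            detector = detector_params(),
                            rise_delta = 1.0,
                            fall_slope = -20,
                            min_support_ms = 200,
                            sync_threshold_s = 0.250) {
  structure(list(algorithm = match.arg(algorithm),
                 mains_hz = mains_hz,
                 rms_window_ms = rms_window_ms,
                 lag_shift_ms = lag_shift_ms,
                 cardiac_removal = match.arg(cardiac_removal),
                 snr_threshold_db = snr_threshold_db,
                 min_activities = min_activities,
                 detector = detector,
                 rise_delta = rise_delta,
                 fall_slope = fall_slope,
                 min_support_ms = min_support_ms,
                 sync_threshold_s = sync_threshold_s),
            class = "vent_config")
}

#' Run the full asynchrony-characterization pipeline
#'
#' Preprocesses the available sEMG channels (powerline + cardiac removal,
#' RMS envelope), detects inspiratory efforts with the selected
#' algorithm(s), gates channels on signal quality, fuses valid channels
#' (earlier onset wins), segments ventilator supports from Paw, classifies
#' every breath and computes the asynchrony index. Deterministic given
#' inputs and config. If no sEMG channel is valid, supports-only output is
#' returned with an undefined asynchrony index.
#'
#' @param rec A [recording()] with `paw` and at least one of `emg_di`,
#'   `emg_para`.
#' @param config A [pipeline_config()].
#' @return List of class `vent_run`: per-algorithm `breaths`
#'   (`vent_breaths`), `ai` ([asynchrony_index()] result), `efforts`
#'   (fused events), plus `supports` and per-channel `quality`.
#' @export
run_pipeline <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "vent_recording"))
  if (!"paw" %in% names(rec$channels))
    stop("vent_segmentation: recording has no 'paw' channel")
  emg_names <- intersect(c("emg_di", "emg_para"), names(rec$channels))
  if (length(emg_names) == 0)
    stop("emg_preprocess: recording has no sEMG channel")

  supports <- segment_supports(rec$channels$paw, config$rise_delta,
                               config$fall_slope, config$min_support_ms)

  envs <- list()
  for (ch in emg_names) {
    x <- remove_powerline(rec$channels[[ch]], config$mains_hz)
    if (config$cardiac_removal == "template")
      x <- suppressWarnings(remove_cardiac(x))
    envs[[ch]] <- compute_envelope(x, config$rms_window_ms,
                                   config$lag_shift_ms)
  }

  algos <- if (config$algorithm == "both") c("triangle", "adaptive")
           else config$algorithm
  out <- list(supports = supports, quality = list(), results = list())
  for (alg in algos) {
    detect <- if (alg == "triangle") detect_triangle else detect_adaptive
    per_ch <- list(); qual <- list()
    for (ch in emg_names) {
      evs <- detect(envs[[ch]], config$detector, source = ch)
      qual[[ch]] <- assess_channel(envs[[ch]], evs,
                                   config$snr_threshold_db,
                                   config$min_activities)
      if (isTRUE(qual[[ch]]$valid)) per_ch[[ch]] <- evs
    }
    out$quality[[alg]] <- qual
    if (length(per_ch) == 0) {
      out$results[[alg]] <- list(
        efforts = effort_events(),
        breaths = classify(NULL, supports, config$sync_threshold_s),
        ai = structure(list(ai = NA_real_, counts = NULL,
                            n_breaths = NA_integer_, undefined = TRUE),
                       class = "vent_ai"))
      next
    }
    fused <- Reduce(fuse_channels, per_ch)
    breaths <- classify(fused, supports, config$sync_threshold_s)
    out$results[[alg]] <- list(efforts = fused, breaths = breaths,
                               ai = asynchrony_index(breaths))
  }
  class(out) <- "vent_run"
  out
}

#' @export
print.vent_run <- function(x, ...) {
  cat(sprintf("<vent_run> %d support(s); algorithms: %s\n",
              nrow(x$supports), paste(names(x$results), collapse = ", ")))
  for (alg in names(x$results)) {
    r <- x$results[[alg]]
    cat(sprintf("  %-9s %3d effort(s), %3d breath record(s), AI = %s\n",
                alg, nrow(r$efforts), nrow(r$breaths),
                if (r$ai$undefined) "undefined" else sprintf("%.3f", r$ai$ai)))
  }
  invisible(x)
}
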