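#' Uniformly sampled time series
#'
#' The backbone container for all signal passing: a numeric vector of samples
#' with a sampling rate (Hz), a start offset `t0` (s) and a unit string.
#' Sample `i` (1-based) sits at time `t0 + (i - 1) / rate`.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds from recording start.
#' @param units Unit string, e.g. `"cmH2O"`, `"L/s"`, `"L"`, `"uV"`.
#' @return An object of class `vent_ts`.
#' @export
time_series <- function(samples, rate, t0 = 0, units = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite")
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         units = as.character(units)),
    class = "vent_ts")
}

#' @export
length.vent_ts <- function(x) length(x$samples)

#' Sample times of a time series
#' @param ts A `vent_ts`.
#' @return Numeric vector of times in seconds, same length as the samples.
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) / ts$rate

#' Duration covered by a time series
#' @param ts A `vent_ts`.
#' @return Span in seconds from first to one-past-last sample.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

# nearest sample index for a time (clamped into range)
ts_index <- function(ts, t) {
  i <- round((t - ts$t0) * ts$rate) + 1
  pmin(pmax(i, 1L), length(ts$samples))
}

#' @export
print.vent_ts <- function(x, ...) {
  cat(sprintf("<vent_ts> %d samples @ %g Hz [%s], t0 = %g s, span %.2f s\n",
              length(x$samples), x$rate, x$units, x$t0, ts_duration(x)))
  invisible(x)
}

#' Multichannel recording
#'
#' A named set of [time_series()] channels (any subset of `paw`, `flow`,
#' `pes`, `emg_di`, `emg_para`, ...) plus free-form metadata. Channels may
#' have different rates (pressures typically 100 Hz, sEMG 1000 Hz) but must
#' cover a common overlapping time span.
#'
#' @param channels Named list of `vent_ts` objects.
#' @param meta Named list of free-form metadata (patient id, mode, ...).
#' @return An object of class `vent_recording`.
#' @export
recording <- function(channels, meta = list()) {
  if (length(channels) == 0L) stop("recording needs at least one channel")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channels must be uniquely named")
  ok <- vapply(channels, inherits, logical(1), what = "vent_ts")
  if (!all(ok)) stop("all channels must be vent_ts objects")
  starts <- vapply(channels, function(ch) ch$t0, numeric(1))
  ends <- vapply(channels, function(ch) ch$t0 + ts_duration(ch), numeric(1))
  if (max(starts) >= min(ends))
    stop("channels do not share an overlapping time span")
  structure(list(channels = channels, meta = meta), class = "vent_recording")
}

#' @export
print.vent_recording <- function(x, ...) {
  cat(sprintf("<vent_recording> %d channel(s): %s\n",
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-9s %7d samples @ %6g Hz [%s]\n",
                nm, length(ch$samples), ch$rate, ch$units))
  }
  invisible(x)
}

#' Expert annotation table
#'
#' Onset times (and optional offsets) per annotator, as used for the expert
#' reference of inspiratory patient effort.
#'
#' @param annotator Character/factor vector of annotator ids.
#' @param onset Numeric onset times in seconds.
#' @param offset Optional numeric offset times (NA allowed).
#' @return A data.frame with class `vent_annotations`, sorted per annotator.
#' @export
annotation_table <- function(annotator, onset, offset = NULL) {
  if (length(annotator) != length(onset))
    stop("`annotator` and `onset` must have the same length")
  df <- data.frame(annotator = as.character(annotator),
                   onset = as.numeric(onset),
                   offset = if (is.null(offset)) NA_real_ else as.numeric(offset))
  df <- df[order(df$annotator, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("vent_annotations", "data.frame")
  df
}

#' Read a multichannel recording from delimited text
#'
#' Text dialect: one file per channel named `<stem>_<channel>.csv`, a single
#' header row, comma- or tab-separated, either an explicit time column `t`
#' (must be uniform) or an implicit index at the rate recorded in the JSON
#' sidecar `<stem>_meta.json`, which also carries units and metadata.
#'
#' @param path Path stem used by [write_recording()] (or a directory/stem).
#' @param channel_map Optional named character vector renaming file channels
#'   to canonical names, e.g. `c(paw = "airway_pressure")`.
#' @return A [recording()].
#' @export
load_recording <- function(path, channel_map = NULL) {
  sidecar <- paste0(path, "_meta.json")
  if (!file.exists(sidecar))
    stop("sidecar not found: ", sidecar)
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  chans <- list()
  for (nm in names(info$channels)) {
    ci <- info$channels[[nm]]
    f <- paste0(path, "_", nm, ".csv")
    if (!file.exists(f)) stop("missing channel file for '", nm, "': ", f)
    first <- readLines(f, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(f, header = TRUE, sep = sep)
    t0 <- if (!is.null(ci$t0)) ci$t0 else 0
    if ("t" %in% names(df)) {
      dt <- diff(df$t)
      if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 / ci$rate * ci$rate)
        if (max(abs(dt - 1 / ci$rate)) > 1e-6)
          stop("non-uniform sampling in text input for channel '", nm, "'")
      t0 <- df$t[1]
    }
    val_col <- setdiff(names(df), "t")[1]
    chans[[nm]] <- time_series(df[[val_col]], rate = ci$rate, t0 = t0,
                               units = if (is.null(ci$units)) "" else ci$units)
  }
  if (!is.null(channel_map)) {
    missing <- setdiff(unname(channel_map), names(chans))
    if (length(missing))
      stop("mapped channel(s) not present in file: ",
           paste(missing, collapse = ", "))
    for (canon in names(channel_map)) {
      names(chans)[names(chans) == channel_map[[canon]]] <- canon
    }
  }
  meta <- info$meta
  recording(chans, meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write a recording as delimited text plus JSON sidecar
#'
#' Inverse of [load_recording()]: one CSV per channel (`t` and value columns,
#' full double precision) and a `<stem>_meta.json` sidecar with rates, units
#' and metadata.
#'
#' @param rec A [recording()].
#' @param path Path stem; files `<stem>_<channel>.csv` and
#'   `<stem>_meta.json` are created.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vent_recording"))
  info <- list(
    channels = lapply(rec$channels, function(ch)
      list(rate = ch$rate, units = ch$units, t0 = ch$t0)),
    meta = rec$meta)
  jsonlite::write_json(info, paste0(path, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    df <- data.frame(t = ts_times(ch), value = ch$samples)
    names(df)[2] <- nm
    utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                       paste0(path, "_", nm, ".csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Band-limited resampling
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) at the smaller Nyquist frequency and the signal
#' re-gridded at the target rate, i.e. ideal band-limited interpolation
#' under the periodic extension. Exact for band-limited input; duration is
#' preserved within one sample period and the mean of a DC signal exactly.
#'
#' @param ts A [time_series()].
#' @param target_rate Target sampling frequency in Hz (> 0).
#' @return A `vent_ts` at (approximately exactly) `target_rate`.
#' @export
resample <- function(ts, target_rate) {
  stopifnot(inherits(ts, "vent_ts"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("`target_rate` must be > 0")
  if (abs(target_rate - ts$rate) < 1e-12) return(ts)
  x <- ts$samples
  n <- length(x)
  if (n < 2) return(time_series(x, target_rate, ts$t0, ts$units))
  m <- max(2L, round(n * target_rate / ts$rate))
  X <- stats::fft(x)
  Y <- complex(m)
  # copy positive/negative frequency bins below both Nyquist limits
  k <- min((n - 1L) %/% 2L, (m - 1L) %/% 2L)
  Y[1] <- X[1]
  if (k >= 1) {
    Y[2:(k + 1)] <- X[2:(k + 1)]
    Y[(m - k + 1):m] <- X[(n - k + 1):n]
  }
  if (m > n && n %% 2 == 0) {
    # split the input Nyquist bin symmetrically when upsampling
    half <- n %/% 2L
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- Conj(X[half + 1]) / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  time_series(y, target_rate, ts$t0, ts$units)
}
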