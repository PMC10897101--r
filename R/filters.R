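# Internal DSP primitives (no signal-processing package in the stack).
# All filters operate on plain numeric vectors; time-series wrapping stays
# in the exported operations.

# causal IIR filter y = filter(b, a, x), direct form via two C-level passes
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  v <- stats::filter(c(rep(0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# zero-phase filtering with odd-reflection padding (filtfilt)
filtfilt_pad <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, max(3L * (length(a) + length(b)), 1000L))
  if (pad < 1L) return(iir_filter(b, a, rev(iir_filter(b, a, rev(x)))))
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# RBJ second-order notch, centre f0 Hz, -3 dB bandwidth bw Hz
design_notch <- function(f0, bw, rate) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) * bw / (2 * f0)     # Q = f0 / bw
  list(b = c(1, -2 * cos(w0), 1), a = c(1 + alpha, -2 * cos(w0), 1 - alpha))
}

# zero-phase FFT band-pass with raised-cosine transitions, reflection padded
fft_bandpass <- function(x, rate, low = NULL, high = NULL, transition = 1) {
  n <- length(x)
  if (n < 4) return(x)
  p <- min(n - 1L, max(16L, ceiling(n / 8)))
  xe <- c(x[(p + 1L):2], x, x[(n - 1L):(n - p)])
  np <- length(xe)
  f <- (seq_len(np) - 1) / np * rate
  f <- pmin(f, rate - f)     # two-sided frequency axis
  g <- rep(1, np)
  ramp <- function(fr, edge, tr) {     # 0 below edge-tr, 1 above edge
    w <- (fr - (edge - tr)) / tr
    pmin(pmax(w, 0), 1)
  }
  if (!is.null(low) && low > 0)
    g <- g * 0.5 * (1 - cos(pi * ramp(f, low, transition)))
  if (!is.null(high) && high < rate / 2) {
    w <- 1 - ramp(f, high + transition, transition)
    g <- g * 0.5 * (1 - cos(pi * w))
  }
  y <- Re(stats::fft(stats::fft(xe) * g, inverse = TRUE)) / np
  y[(p + 1L):(p + n)]
}

# idempotent zero-phase mains suppressor: zeroes +/- halfwidth Hz around
# every mains harmonic in the spectrum (used for estimation copies)
fft_mains_mask <- function(x, rate, mains_hz, halfwidth = 2) {
  n <- length(x)
  if (n < 8 || rate <= 2 * mains_hz) return(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  g <- rep(1, n)
  for (f0 in seq(mains_hz, rate / 2, by = mains_hz))
    g[abs(f - f0) <= halfwidth] <- 0
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# causal moving RMS over an integer window, start padded by reflection
moving_rms <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  pad <- min(w - 1L, n - 1L)
  xe <- c(x[(pad + 1L):2], x)
  ma <- stats::filter(xe^2, rep(1 / w, w), method = "convolution", sides = 1)
  sqrt(pmax(as.numeric(ma)[(pad + 1L):(pad + n)], 0))
}

# cumulative trapezoidal integral of y sampled at constant dt
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * dt))
}

# simple peak finder: local maxima above `thresh` separated by >= min_dist
find_peaks <- function(x, thresh = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
                 x[2:(n - 1)] >= thresh) + 1L
  if (length(idx) <= 1 || min_dist <= 1) return(idx)
  keep <- integer(0)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  taken <- logical(n)
  for (i in ord) {
    lo <- max(1L, i - min_dist + 1L); hi <- min(n, i + min_dist - 1L)
    if (!any(taken[lo:hi])) { keep <- c(keep, i); taken[i] <- TRUE }
  }
  sort(keep)
}
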