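# Internal signal-processing and misc helpers shared across modules.

#' @useDynLib stresswalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx convolve cor cor.test ecdf mad median pnorm
#'   predict qnorm quantile rexp rlnorm rnorm runif rpois sd var setNames
#'   coef dnorm plogis qt complete.cases
#' @importFrom utils head tail write.csv read.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible stage seed from a master seed
#'
#' Mixes a master seed with a character tag so that independent pipeline
#' stages get distinct but reproducible streams. Result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer master seed.
#' @param tag character stage label.
#' @return integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621 + 11) %% 2147483647)
}

# Odd-length windowed-sinc (Hamming) low-pass FIR; fc in cycles/sample (< 0.5).
fir_lowpass <- function(n_taps, fc) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- seq.int(-m, m)
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

# Band-pass as a difference of two low-pass designs; f_lo < f_hi in
# cycles/sample.
fir_bandpass <- function(n_taps, f_lo, f_hi) {
  fir_lowpass(n_taps, f_hi) - fir_lowpass(n_taps, f_lo)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Single-pass "same" convolution with a symmetric odd-length kernel.
# Edge padding: "even" mirrors the signal (safe for impulse-like signals
# such as ECG); "odd" anti-symmetric reflection continues slow oscillations
# without amplitude loss (filtfilt convention, used for respiration).
fir_filter_same <- function(x, h, pad_mode = "even") {
  n <- length(x)
  m <- (length(h) - 1) / 2
  pad <- min(m, n - 1)
  xe <- if (pad_mode == "odd") {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  }
  y <- fft_conv(xe, h)
  y[(pad + length(h) - m):(pad + length(h) - m + n - 1)]
}

# Full linear convolution via FFT at a power-of-2 size (arbitrary lengths
# can hit slow mixed-radix FFT sizes).
fft_conv <- function(x, h) {
  nfull <- length(x) + length(h) - 1
  m <- stats::nextn(nfull, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - length(x)))) *
                       stats::fft(c(h, numeric(m - length(h)))),
                     inverse = TRUE)) / m
  y[seq_len(nfull)]
}

# Zero-phase two-pass filtering (forward + backward), MATLAB filtfilt style.
filtfilt_fir <- function(x, h, pad_mode = "even") {
  y <- fir_filter_same(x, h, pad_mode)
  rev(fir_filter_same(rev(y), h, pad_mode))
}

# Centered moving average over a window of `k` samples (k made odd).
# Trajectory smoothing uses odd padding so constant-velocity paths keep
# their slope at the edges.
moving_average <- function(x, k, pad_mode = "even") {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  fir_filter_same(x, rep(1 / k, k), pad_mode)
}

# scipy/MATLAB-findpeaks-style peak finding: local maxima filtered by
# absolute height, prominence, minimum inter-peak distance (samples, greedy
# from highest) and minimum width (samples) at half prominence.
find_peaks <- function(x, height = -Inf, distance = 1, min_width = 0,
                       min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= height]
  if (!length(cand)) return(integer(0))

  if (min_width > 0 || min_prominence > 0) {
    keep <- rep(TRUE, length(cand))
    for (j in seq_along(cand)) {
      p <- cand[j]
      # prominence bases: walk out to the first higher sample on each side
      li <- p; lmin <- x[p]
      while (li > 1 && x[li - 1] <= x[p]) { li <- li - 1; lmin <- min(lmin, x[li]) }
      ri <- p; rmin <- x[p]
      while (ri < n && x[ri + 1] <= x[p]) { ri <- ri + 1; rmin <- min(rmin, x[ri]) }
      prom <- x[p] - max(lmin, rmin)
      if (prom < min_prominence) { keep[j] <- FALSE; next }
      if (min_width > 0) {
        ref <- x[p] - prom / 2
        # interpolated half-prominence crossings
        wl <- p
        while (wl > li && x[wl - 1] > ref) wl <- wl - 1
        lpos <- if (wl > li && x[wl - 1] <= ref) {
          (wl - 1) + (ref - x[wl - 1]) / (x[wl] - x[wl - 1])
        } else wl
        wr <- p
        while (wr < ri && x[wr + 1] > ref) wr <- wr + 1
        rpos <- if (wr < ri && x[wr + 1] <= ref) {
          wr + (x[wr] - ref) / (x[wr] - x[wr + 1])
        } else wr
        keep[j] <- (rpos - lpos) >= min_width
      }
    }
    cand <- cand[keep]
  }
  if (!length(cand) || distance <= 1) return(cand)

  # enforce minimum distance greedily from the highest peak down
  ord <- cand[order(x[cand], decreasing = TRUE)]
  blocked <- logical(n)
  taken <- logical(length(ord))
  for (j in seq_along(ord)) {
    p <- ord[j]
    if (blocked[p]) next
    taken[j] <- TRUE
    blocked[max(1, p - distance + 1):min(n, p + distance - 1)] <- TRUE
  }
  sort(ord[taken])
}

# Wrap angle differences into (-180, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Linear interpolation over flagged entries; endpoints take the nearest
# unflagged value. `flag` logical, at least one FALSE required.
interp_flagged <- function(x, flag) {
  good <- which(!flag)
  if (!length(good)) return(x)
  approx(good, x[good], xout = seq_along(x), rule = 2)$y
}
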