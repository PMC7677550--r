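# ECG / respiration processing: decimation, Pan-Tompkins R-peak detection,
# 3-SD RR artifact cleaning, time-domain HRV formulas and per-segment
# cardiorespiratory summaries.

#' Physiological waveform containers
#'
#' Thin containers holding an amplitude vector, its sampling rate and a
#' start time.
#'
#' @param samples numeric amplitude vector (finite).
#' @param fs sampling rate, Hz (> 0).
#' @param t0 start time, s.
#' @return object of class `ecg_signal` / `resp_signal` (both inherit
#'   `physio_signal`).
#' @export
ecg_signal <- function(samples, fs, t0 = 0) {
  new_signal(samples, fs, t0, "ecg_signal")
}

#' @rdname ecg_signal
#' @export
resp_signal <- function(samples, fs, t0 = 0) {
  new_signal(samples, fs, t0, "resp_signal")
}

new_signal <- function(samples, fs, t0, cls) {
  if (fs <= 0) stopf("fs must be positive")
  if (!all(is.finite(samples))) stopf("samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = c(cls, "physio_signal"))
}

signal_duration <- function(signal) length(signal$samples) / signal$fs

#' Decimate a waveform
#'
#' Anti-alias low-pass FIR (30-tap Hamming windowed sinc with cutoff at the
#' new Nyquist frequency, applied forward and backward for zero phase)
#' followed by downsampling, i.e. the classic FIR decimator: 1000 Hz ECG at
#' factor 2 gives 500 Hz, respiration at factor 10 gives 100 Hz.
#'
#' @param signal an [ecg_signal()] or [resp_signal()].
#' @param factor integer decimation factor (>= 1; 1 is the identity).
#' @return signal of the same class at `fs / factor`.
#' @export
decimate_signal <- function(signal, factor) {
  if (factor < 1 || factor != round(factor)) stopf("factor must be a positive integer")
  if (factor == 1) return(signal)
  h <- fir_lowpass(31, 0.5 / factor)
  y <- filtfilt_fir(signal$samples, h)
  out <- signal
  out$samples <- y[seq(1, length(y), by = factor)]
  out$fs <- signal$fs / factor
  out
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Band-pass (5-15 Hz), five-point derivative, squaring, 150 ms moving
#' window integration, then adaptive dual thresholds with search-back and a
#' 200 ms refractory period. Each detection is refined to the local maximum
#' of the raw ECG within +/- 25 ms.
#'
#' @param ecg an [ecg_signal()] with `fs >= 250` and duration `>= 5` s.
#' @param band band-pass edges, Hz.
#' @param refractory refractory period, s.
#' @param integration_window moving integration window, s.
#' @param searchback_factor missed-beat search-back trigger as a multiple of
#'   the running average RR.
#' @return object of class `beat_series`: list with `r_times` (s, strictly
#'   increasing) and `fs`.
#' @export
detect_r_peaks <- function(ecg, band = c(5, 15), refractory = 0.2,
                           integration_window = 0.15,
                           searchback_factor = 1.66) {
  fs <- ecg$fs
  if (fs < 250) stopf("fs must be >= 250 Hz")
  if (signal_duration(ecg) < 5) stopf("signal must be at least 5 s long")
  x <- ecg$samples
  n <- length(x)
  if (sd(x) < 1e-12) {
    warning("flat ECG signal: no beats detected")
    return(structure(list(r_times = numeric(0), fs = fs), class = "beat_series"))
  }

  ntaps <- round(fs * 0.3); if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  bp <- filtfilt_fir(x, fir_bandpass(ntaps, band[1] / fs, band[2] / fs))
  # Pan-Tompkins five-point derivative, aligned to zero delay
  dk <- c(2, 1, 0, -1, -2) * fs / 8
  der <- fir_filter_same(bp, dk)
  sq <- der^2
  win <- max(3, round(integration_window * fs))
  mwi <- moving_average(sq, win)

  refr <- round(refractory * fs)
  cand <- find_peaks(mwi, distance = refr)
  if (!length(cand)) {
    warning("no candidate peaks found")
    return(structure(list(r_times = numeric(0), fs = fs), class = "beat_series"))
  }

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.6 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)

  beats <- integer(0)
  rr_hist <- numeric(0)
  last_cand_kept <- 0L
  for (j in seq_along(cand)) {
    p <- cand[j]; h <- mwi[p]
    if (length(beats) && (p - tail(beats, 1)) < refr) next
    if (h > thr1()) {
      beats <- c(beats, p)
      spki <- 0.125 * h + 0.875 * spki
      if (length(beats) > 1) {
        rr_hist <- tail(c(rr_hist, diff(tail(beats, 2))), 8)
      }
      last_cand_kept <- j
    } else {
      npki <- 0.125 * h + 0.875 * npki
      # search-back: if the expected beat is overdue, accept the largest
      # skipped candidate above half threshold
      if (length(beats) && length(rr_hist)) {
        overdue <- (p - tail(beats, 1)) > searchback_factor * mean(rr_hist)
        if (overdue) {
          back <- cand[cand > tail(beats, 1) + refr & cand <= p]
          if (length(back)) {
            bb <- back[which.max(mwi[back])]
            if (mwi[bb] > 0.5 * thr1()) {
              beats <- c(beats, bb)
              spki <- 0.25 * mwi[bb] + 0.75 * spki
              rr_hist <- tail(c(rr_hist, diff(tail(beats, 2))), 8)
            }
          }
        }
      }
    }
  }
  beats <- sort(unique(beats))
  if (!length(beats)) {
    warning("no beats exceeded the adaptive threshold")
    return(structure(list(r_times = numeric(0), fs = fs), class = "beat_series"))
  }

  # two-stage fiducial refinement: locate the QRS energy peak (squared
  # band-passed signal) within +/- 75 ms of the integrator peak, then the
  # raw-ECG local maximum within +/- 25 ms
  half75 <- round(0.075 * fs)
  half <- round(0.025 * fs)
  refined <- vapply(beats, function(p) {
    lo <- max(1L, p - half75); hi <- min(n, p + half75)
    p2 <- lo + which.max(sq[lo:hi]) - 1L
    lo <- max(1L, p2 - half); hi <- min(n, p2 + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  refined <- refined[keep]
  structure(list(r_times = ecg$t0 + (refined - 1) / fs, fs = fs),
            class = "beat_series")
}

#' Clean an RR series with a 3-standard-deviation filter
#'
#' Intervals deviating more than three SDs from the mean (both moments
#' taken over the raw interval series in a single pass) are flagged as
#' artifacts and replaced by linear interpolation between the nearest
#' unflagged neighbors; flagged endpoints take the nearest unflagged value.
#'
#' @param beats a [detect_r_peaks()] result (>= 4 beats), or a numeric
#'   vector of beat times in seconds.
#' @param n_sd rejection threshold in SD units.
#' @return object of class `nn_series`: list with `intervals` (ms),
#'   `artifact_flags` and `onset_times` (s).
#' @export
clean_rr <- function(beats, n_sd = 3) {
  r_times <- if (inherits(beats, "beat_series")) beats$r_times else as.numeric(beats)
  if (length(r_times) < 4) stopf("need at least 4 beats to clean an RR series")
  raw <- diff(r_times) * 1000
  m <- mean(raw); s <- sd(raw)
  flags <- if (s > 0) abs(raw - m) > n_sd * s else rep(FALSE, length(raw))
  intervals <- if (any(flags) && !all(flags)) interp_flagged(raw, flags) else raw
  structure(list(intervals = intervals, artifact_flags = flags,
                 onset_times = r_times[-length(r_times)]),
            class = "nn_series")
}

#' NN series constructor
#'
#' @param intervals NN intervals, ms (> 0).
#' @param artifact_flags per-interval logical flags (interpolated values).
#' @param onset_times onset time of each interval, s.
#' @return object of class `nn_series`.
#' @export
nn_series <- function(intervals, artifact_flags = rep(FALSE, length(intervals)),
                      onset_times = cumsum(c(0, head(intervals, -1))) / 1000) {
  if (any(intervals <= 0)) stopf("intervals must be positive")
  structure(list(intervals = as.numeric(intervals),
                 artifact_flags = artifact_flags,
                 onset_times = onset_times), class = "nn_series")
}

nn_intervals <- function(nn) {
  if (inherits(nn, "nn_series")) nn$intervals else as.numeric(nn)
}

#' Time-domain HRV metrics
#'
#' `rmssd()` is the root mean square of successive NN differences (ms),
#' `sdnn()` the sample standard deviation of the NN intervals (ms,
#' n - 1 denominator), `hrv_ti()` the HRV triangular index (total interval
#' count divided by the maximal bin count of the interval histogram with
#' 7.8125 ms = 1/128 s bins anchored at 0), and `heart_rate()` is
#' 60000 / mean NN (bpm).
#'
#' @param nn an [nn_series()] or numeric vector of NN intervals in ms.
#' @return numeric scalar.
#' @export
rmssd <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 3) stopf("rmssd needs at least 3 intervals")
  sqrt(mean(diff(x)^2))
}

#' @rdname rmssd
#' @export
sdnn <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 2) stopf("sdnn needs at least 2 intervals")
  sd(x)
}

#' @rdname rmssd
#' @param bin_width histogram bin width, ms (1/128 s per HRV standards).
#' @export
hrv_ti <- function(nn, bin_width = 1000 / 128) {
  x <- nn_intervals(nn)
  if (length(x) < 2) stopf("hrv_ti needs at least 2 intervals")
  counts <- table(floor(x / bin_width))
  length(x) / max(counts)
}

#' @rdname rmssd
#' @export
heart_rate <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 1) stopf("heart_rate needs at least 1 interval")
  60000 / mean(x)
}

#' Estimate respiration rate from a respiration waveform
#'
#' Band-pass FIR (0.17-0.73 Hz, zero phase), then peak detection: peak
#' prominence must reach one robust SD (1.4826 x MAD) of the filtered
#' series, peaks must be separated by at least 0.8 s and be at least 0.4 s
#' wide at half prominence (MATLAB findpeaks conventions). The
#' rate is the peak count divided by the duration, in breaths/min. Missing
#' (`NA`, with a warning) results: signals whose band-passed residue keeps
#' under 5% of the raw power (out-of-band oscillation), no qualifying
#' peaks, or an estimated rate outside the passband-implied range
#' (10.2-43.8 breaths/min).
#'
#' @param resp a [resp_signal()] (>= 10 s, fs >= 25 Hz).
#' @param band passband edges, Hz.
#' @param min_separation minimum inter-peak gap, s.
#' @param min_width minimum peak width at half prominence, s.
#' @return breaths/min, or `NA` (attribute `n_peaks` carries the count).
#' @export
respiration_rate <- function(resp, band = c(0.17, 0.73),
                             min_separation = 0.8, min_width = 0.4) {
  fs <- resp$fs
  dur <- signal_duration(resp)
  if (fs < 25) stopf("fs must be >= 25 Hz")
  if (dur < 10) stopf("respiration signal must be at least 10 s long")
  ntaps <- round(fs * 24); if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  ntaps <- min(ntaps, 2 * length(resp$samples) - 1)
  filt <- filtfilt_fir(resp$samples, fir_bandpass(ntaps, band[1] / fs, band[2] / fs),
                       pad_mode = "odd")
  rsd <- mad(filt)
  # an out-of-band oscillation is attenuated to a sliver of the raw power;
  # what remains is noise, so no rate can be read off it
  if (rsd < 1e-12 || var(filt) < 0.05 * var(resp$samples)) {
    warning("respiration signal has no in-band content")
    return(structure(NA_real_, n_peaks = 0L))
  }
  # odd-reflect by one low-edge period so boundary peaks keep their full
  # prominence, then count only peaks inside the original span
  np <- length(filt)
  pad <- min(round(fs / band[1]), np - 1)
  ext <- c(2 * filt[1] - filt[(pad + 1):2], filt,
           2 * filt[np] - filt[(np - 1):(np - pad)])
  pk <- find_peaks(ext, min_prominence = rsd,
                   distance = round(min_separation * fs),
                   min_width = min_width * fs)
  pk <- pk[pk > pad & pk <= pad + np] - pad
  if (!length(pk)) {
    warning("no qualifying respiration peaks")
    return(structure(NA_real_, n_peaks = 0L))
  }
  rate <- length(pk) / dur * 60
  lo <- band[1] * 60; hi <- band[2] * 60
  if (rate < lo || rate > hi) {
    warning(sprintf("estimated rate %.1f breaths/min is outside the %.1f-%.1f passband; flagged missing",
                    rate, lo, hi))
    return(structure(NA_real_, n_peaks = length(pk)))
  }
  structure(rate, n_peaks = length(pk))
}

#' Per-segment cardiorespiratory summaries
#'
#' Computes HR, RMSSD, SDNN, HRVTi and respiration rate for each requested
#' segment. Only NN intervals whose onset lies inside the segment
#' contribute; segments with fewer than 3 usable intervals yield missing
#' values, flagged. The default segmentation splits the recording into
#' consecutive 30-s blocks (three for a 90-s session).
#'
#' @param nn an [nn_series()].
#' @param resp a [resp_signal()], or NULL to skip the respiration column.
#' @param segments list of `c(start, end)` pairs in seconds;
#'   non-overlapping. Default: 30-s blocks covering the recording.
#' @return data.frame with one row per segment: `start, end, n_beats, hr,
#'   rmssd, sdnn, hrvti, rr, missing`.
#' @export
segment_summary <- function(nn, resp = NULL, segments = NULL) {
  if (is.null(segments)) {
    dur <- if (!is.null(resp)) signal_duration(resp) else
      max(nn$onset_times) + mean(nn$intervals) / 1000
    edges <- seq(0, dur, by = 30)
    if (tail(edges, 1) < dur) edges <- c(edges, dur)
    segments <- lapply(seq_len(length(edges) - 1),
                       function(i) c(edges[i], edges[i + 1]))
  }
  if (!length(segments)) stopf("segment list must be non-empty")
  starts <- vapply(segments, `[`, numeric(1), 1)
  ends <- vapply(segments, `[`, numeric(1), 2)
  if (any(ends <= starts)) stopf("segments must have end > start")
  ord <- order(starts)
  if (any(starts[ord][-1] < ends[ord][-length(ord)] - 1e-9)) {
    stopf("segments must be non-overlapping")
  }

  rows <- lapply(seq_along(segments), function(i) {
    s <- starts[i]; e <- ends[i]
    idx <- which(nn$onset_times >= s & nn$onset_times < e)
    x <- nn$intervals[idx]
    rr <- NA_real_
    if (!is.null(resp) && (e - s) >= 10) {
      i0 <- max(1, floor((s - resp$t0) * resp$fs) + 1)
      i1 <- min(length(resp$samples), ceiling((e - resp$t0) * resp$fs))
      seg_sig <- resp_signal(resp$samples[i0:i1], resp$fs, t0 = s)
      rr <- suppressWarnings(as.numeric(respiration_rate(seg_sig)))
    }
    if (length(x) < 3) {
      return(data.frame(start = s, end = e, n_beats = length(x) + 1L,
                        hr = NA_real_, rmssd = NA_real_, sdnn = NA_real_,
                        hrvti = NA_real_, rr = rr, missing = TRUE))
    }
    data.frame(start = s, end = e, n_beats = length(x) + 1L,
               hr = heart_rate(x), rmssd = rmssd(x), sdnn = sdnn(x),
               hrvti = hrv_ti(x), rr = rr, missing = FALSE)
  })
  do.call(rbind, rows)
}
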