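#' Eligibility of a transient for decay analysis
#'
#' A trial-averaged response qualifies for kinetics estimation only if its
#' peak during the last 1 s of the stimulus exceeds the baseline mean by more
#' than four baseline standard deviations. If the baseline has zero variance
#' any peak above baseline qualifies.
#'
#' @param trace dF/F0 `ca_trace`.
#' @param baseline_window length-2 start/end times (s) of the pre-stimulus
#'   baseline (typically the 1 s before stimulus onset).
#' @param stim_window length-2 start/end times (s) of the stimulus.
#' @param k_sd threshold in baseline SDs (default 4).
#' @param last_s length of the end-of-stimulus window inspected (default 1).
#' @return logical.
#' @export
decay_eligibility <- function(trace, baseline_window, stim_window,
                              k_sd = 4, last_s = 1) {
  stopifnot(inherits(trace, "ca_trace"))
  bi <- window_idx(trace, baseline_window[1], baseline_window[2])
  si <- window_idx(trace, max(stim_window[2] - last_s, stim_window[1]),
                   stim_window[2])
  if (!length(bi) || !length(si)) stop("windows select no samples")
  b <- trace$samples[bi]
  peak <- max(trace$samples[si])
  (peak - mean(b)) > k_sd * stats::sd(b)
}

# Locate the first downward crossing of `level` at/after index i0; linear
# interpolation between the bracketing samples. Returns time (s) or NA.
first_down_crossing <- function(x, fs, i0, level, t0 = 0) {
  n <- length(x)
  if (i0 >= n) return(NA_real_)
  for (i in (i0 + 1L):n) {
    if (x[i] <= level) {
      if (x[i - 1L] == x[i]) return(t0 + (i - 1L) / fs)
      frac <- (x[i - 1L] - level) / (x[i - 1L] - x[i])
      return(t0 + (i - 2L + frac) / fs)
    }
  }
  NA_real_
}

#' Half-decay time by linear interpolation
#'
#' Finds the peak (global maximum at or after `peak_time`), subtracts
#' `baseline`, and returns the time from the peak to the first crossing of
#' half the baseline-subtracted peak, located by linear interpolation
#' between the bracketing samples.
#'
#' @param trace dF/F0 `ca_trace`.
#' @param peak_time search for the peak at or after this time (s); default
#'   start of trace.
#' @param baseline baseline level subtracted before halving (default 0).
#' @return list: `half_decay_s` (NA if censored), `peak`, `peak_time`,
#'   `censored` (TRUE when the trace never falls to half-peak).
#' @export
half_decay_time <- function(trace, peak_time = NULL, baseline = 0) {
  stopifnot(inherits(trace, "ca_trace"))
  tt <- trace_times(trace)
  if (is.null(peak_time)) peak_time <- tt[1]
  cand <- which(tt >= peak_time - 1e-9)
  if (!length(cand)) stop("peak_time is past the end of the trace")
  ip <- cand[which.max(trace$samples[cand])]
  peak <- trace$samples[ip]
  if (peak <= baseline) stop("trace does not rise above baseline")
  level <- baseline + (peak - baseline) / 2
  tc <- first_down_crossing(trace$samples, trace$fs, ip, level, trace$t0)
  list(half_decay_s = if (is.na(tc)) NA_real_ else tc - tt[ip],
       peak = peak, peak_time = tt[ip], censored = is.na(tc))
}

#' Half-rise time by linear interpolation
#'
#' Symmetric to [half_decay_time()]: finds the peak at or after
#' `event_time` and returns the time from `event_time` to the first upward
#' crossing of half the baseline-subtracted peak.
#'
#' @param trace dF/F0 `ca_trace`.
#' @param event_time event (e.g. first-spike or stimulus) time, seconds.
#' @param baseline baseline level (default 0).
#' @return list: `half_rise_s` (NA if censored), `peak`, `censored`.
#' @export
half_rise_time <- function(trace, event_time = NULL, baseline = 0) {
  stopifnot(inherits(trace, "ca_trace"))
  tt <- trace_times(trace)
  if (is.null(event_time)) event_time <- tt[1]
  cand <- which(tt >= event_time - 1e-9)
  if (!length(cand)) stop("event_time is past the end of the trace")
  ip <- cand[which.max(trace$samples[cand])]
  peak <- trace$samples[ip]
  if (peak <= baseline)
    return(list(half_rise_s = NA_real_, peak = peak, censored = TRUE))
  level <- baseline + (peak - baseline) / 2
  x <- trace$samples
  tc <- NA_real_
  for (i in cand[1]:ip) {
    if (x[i] >= level) {
      if (i == cand[1] || x[i] == x[i - 1L]) { tc <- tt[i]; break }
      frac <- (level - x[i - 1L]) / (x[i] - x[i - 1L])
      tc <- tt[i - 1L] + frac / trace$fs
      break
    }
  }
  list(half_rise_s = if (is.na(tc)) NA_real_ else tc - event_time,
       peak = peak, censored = is.na(tc))
}

#' Single-exponential decay fit
#'
#' Least-squares fit of `A * exp(-t / tau)` to a decaying trace segment.
#' Goodness is the RMS residual normalized by the fitted amplitude; callers
#' typically keep fits with goodness below 0.1.
#'
#' @param trace `ca_trace` holding the decaying segment (time measured from
#'   its first sample).
#' @param goodness_max threshold used to set the `ok` flag (default 0.1).
#' @return list: `amplitude`, `tau_s`, `goodness`, `ok`, `converged`.
#' @export
fit_exp_decay <- function(trace, goodness_max = 0.1) {
  stopifnot(inherits(trace, "ca_trace"))
  y <- trace$samples
  if (length(y) < 5) stop("need at least 5 samples")
  if (y[1] <= 0) stop("initial value must be positive")
  tt <- trace_times(trace) - trace$t0
  pos <- y > 0
  sl <- if (sum(pos) >= 2) stats::coef(stats::lm(log(y[pos]) ~ tt[pos]))[2]
        else -1
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tt)) / 2
  # warnOnly keeps non-converged fits so the goodness flag can report them
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ a * exp(-tt / tau), start = list(a = y[1], tau = tau0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(amplitude = NA_real_, tau_s = NA_real_, goodness = Inf,
                ok = FALSE, converged = FALSE))
  cf <- stats::coef(fit)
  g <- sqrt(mean(stats::residuals(fit)^2)) / abs(cf[["a"]])
  list(amplitude = cf[["a"]], tau_s = cf[["tau"]], goodness = g,
       ok = is.finite(g) && g < goodness_max,
       converged = fit$convInfo$isConv)
}

#' Stimulus-tracking Fourier amplitude
#'
#' Magnitude spectrum of the stimulus-period trace normalized to the
#' amplitude at 0 Hz (rectangular window, no padding). Reports the
#' normalized amplitude at the frequency bin nearest the stimulus frequency;
#' for `b + a*cos(2 pi f t)` over an integer number of cycles this equals
#' `a / (2b)`.
#'
#' @param trace dF/F0 `ca_trace` restricted to the stimulation period. The
#'   spectrum is computed on `1 + dff`, whose 0 Hz component is the mean
#'   fluorescence, so traces with zero-mean dF/F0 remain well defined;
#'   pass `offset = 0` to use the raw samples.
#' @param f_stim stimulus frequency, Hz (must satisfy `fs > 2 * f_stim`).
#' @param offset constant added to the samples before the transform
#'   (default 1, i.e. operate on F/F0).
#' @return list: `freq_hz`, `spectrum` (normalized magnitudes up to
#'   Nyquist), `amp_at_f_stim`, `f_bin_hz`.
#' @export
fourier_tracking <- function(trace, f_stim, offset = 1) {
  stopifnot(inherits(trace, "ca_trace"), f_stim > 0)
  x <- trace$samples + offset
  n <- length(x)
  if (n < 2 / f_stim * trace$fs)
    stop("trace must cover at least 2 stimulus cycles")
  if (trace$fs <= 2 * f_stim) stop("sampling rate below Nyquist for f_stim")
  mag <- Mod(stats::fft(x))
  if (mag[1] == 0) {
    warning("zero mean; normalized spectrum undefined")
    return(list(freq_hz = NA, spectrum = NA, amp_at_f_stim = NA_real_,
                f_bin_hz = NA_real_))
  }
  nb <- floor(n / 2) + 1L
  freq <- (seq_len(nb) - 1L) * trace$fs / n
  spec <- mag[seq_len(nb)] / mag[1]
  ib <- which.min(abs(freq - f_stim))
  list(freq_hz = freq, spectrum = spec, amp_at_f_stim = spec[ib],
       f_bin_hz = freq[ib])
}
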