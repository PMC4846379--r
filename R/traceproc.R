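#' Neuropil correction by scaled subtraction
#'
#' Removes out-of-focus contamination from a somatic ROI trace:
#' `F_cell_true(t) = F_cell_measured(t) - r * F_neuropil(t)`.
#'
#' @param f_meas measured cell `ca_trace`.
#' @param f_np surrounding-neuropil `ca_trace`, same length and frame rate.
#' @param r contamination coefficient in `[0, 1)` (default 0.7).
#' @return corrected `ca_trace`.
#' @export
neuropil_correct <- function(f_meas, f_np, r = 0.7) {
  stopifnot(inherits(f_meas, "ca_trace"), inherits(f_np, "ca_trace"),
            r >= 0, r < 1)
  if (length(f_meas$samples) != length(f_np$samples) ||
      abs(f_meas$fs - f_np$fs) > 1e-9)
    stop("cell and neuropil traces must share length and frame rate")
  ca_trace(f_meas$samples - r * f_np$samples, f_meas$fs, f_meas$t0)
}

#' Eligibility of a cell for neuropil correction
#'
#' A cell qualifies only if its baseline fluorescence exceeds the surrounding
#' neuropil baseline by more than the margin (default 3%); otherwise F0
#' cannot be estimated reliably and the cell is excluded. Baselines are means
#' over the supplied pre-stimulus windows (the same windows used for F0).
#'
#' @param f_meas,f_np cell and neuropil `ca_trace`s.
#' @param baseline_windows two-column matrix or data.frame of window start /
#'   end times (seconds); multiple rows are pooled.
#' @param margin required fractional excess (default 0.03).
#' @return list: `eligible` (logical), `ratio` (cell/neuropil baseline).
#' @export
check_eligibility <- function(f_meas, f_np, baseline_windows, margin = 0.03) {
  stopifnot(margin >= 0)
  bw <- as.matrix(baseline_windows)
  idx <- unlist(lapply(seq_len(nrow(bw)),
                       function(i) window_idx(f_meas, bw[i, 1], bw[i, 2])))
  if (!length(idx)) stop("baseline windows select no samples")
  b_cell <- mean(f_meas$samples[idx])
  b_np <- mean(f_np$samples[idx])
  ratio <- b_cell / b_np
  list(eligible = b_cell > (1 + margin) * b_np, ratio = ratio)
}

#' Baseline fluorescence F0 over a time window
#'
#' Mean of the samples whose times fall in `[window[1], window[2]]`; for
#' visual trials this is the 1 s period immediately before grating onset.
#'
#' @param trace a `ca_trace`.
#' @param window length-2 numeric, start and end time in seconds.
#' @return scalar F0.
#' @export
compute_f0 <- function(trace, window) {
  stopifnot(inherits(trace, "ca_trace"), length(window) == 2)
  idx <- window_idx(trace, window[1], window[2])
  if (!length(idx)) stop("F0 window selects no samples")
  mean(trace$samples[idx])
}

#' Convert fluorescence to dF/F0
#'
#' @param trace a `ca_trace` of fluorescence.
#' @param f0 baseline fluorescence (> 0), e.g. from [compute_f0()].
#' @return `ca_trace` of `(F - F0)/F0`.
#' @export
compute_dff <- function(trace, f0) {
  stopifnot(inherits(trace, "ca_trace"))
  if (!is.finite(f0) || f0 <= 0)
    stop("F0 must be positive; exclude the cell upstream")
  ca_trace((trace$samples - f0) / f0, trace$fs, trace$t0)
}

#' Centered moving average (display smoothing)
#'
#' k-point centered mean with truncated windows at the edges. Intended for
#' display only; quantitative estimators in this package operate on
#' unsmoothed traces.
#'
#' @param trace a `ca_trace`.
#' @param k odd window length in frames (default 3).
#' @return smoothed `ca_trace`.
#' @export
moving_average <- function(trace, k = 3L) {
  stopifnot(inherits(trace, "ca_trace"))
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("`k` must be odd and >= 1")
  x <- trace$samples
  n <- length(x)
  half <- (k - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
  ca_trace(out, trace$fs, trace$t0)
}

#' Linear spectral unmixing of two imaging channels
#'
#' Observed channels are modeled as `observed = M %*% true` per time point;
#' this applies `solve(M)` to recover the true channel signals (e.g. red
#' bleed-through into green under single-wavelength excitation).
#'
#' @param red,green observed-channel `ca_trace`s, same length and rate.
#' @param mixing 2x2 mixing matrix (row = observed channel, column = true
#'   channel; order red, green).
#' @return list with unmixed `red` and `green` traces.
#' @export
unmix_channels <- function(red, green, mixing) {
  stopifnot(inherits(red, "ca_trace"), inherits(green, "ca_trace"),
            is.matrix(mixing), all(dim(mixing) == c(2, 2)))
  if (length(red$samples) != length(green$samples) ||
      abs(red$fs - green$fs) > 1e-9)
    stop("channel traces must share length and frame rate")
  if (abs(det(mixing)) < 1e-12) stop("mixing matrix is singular")
  inv <- solve(mixing)
  obs <- rbind(red$samples, green$samples)
  tru <- inv %*% obs
  list(red = ca_trace(tru[1, ], red$fs, red$t0),
       green = ca_trace(tru[2, ], green$fs, green$t0))
}
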