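#' Uniformly sampled fluorescence trace
#'
#' Light container for a single ROI fluorescence time series. Samples are in
#' arbitrary fluorescence units (or dF/F0 where stated by the producing
#' function), sampled at `fs` frames per second starting at `t0` seconds.
#'
#' @param samples numeric vector of finite fluorescence values.
#' @param fs sampling rate, frames/s (> 0).
#' @param t0 time of the first sample, seconds.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("trace samples must be finite")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) length(x$samples)

#' Sample times of a trace
#' @param x a `ca_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "ca_trace"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

# Coerce numeric input to ca_trace when fs supplied alongside; internal.
as_trace <- function(x, fs = NULL, t0 = 0) {
  if (inherits(x, "ca_trace")) return(x)
  if (is.null(fs)) stop("numeric input requires `fs`")
  ca_trace(x, fs, t0)
}

# Indices of samples whose time lies in [from, to]; internal.
window_idx <- function(trace, from, to) {
  tt <- trace_times(trace)
  which(tt >= from - 1e-9 & tt <= to + 1e-9)
}
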