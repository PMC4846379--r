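#' Per-indicator AP-bin schedule for event extraction
#'
#' Burst time windows grow with AP count: jRGECO1a-style, 100 ms for 2 APs
#' plus 25 ms per additional AP up to 250 ms at 8 APs; jRCaMP1a-style,
#' 150 ms for 2 APs plus 50 ms per additional AP, capped at 350 ms for
#' 6-8 APs.
#'
#' @param indicator "jRGECO1a" or "jRCaMP1a" (style families).
#' @return function `n -> bin width in seconds` (n >= 2), also accepting
#'   vectors.
#' @export
ap_bin_schedule <- function(indicator = c("jRGECO1a", "jRCaMP1a")) {
  indicator <- match.arg(indicator)
  if (indicator == "jRGECO1a") {
    function(n) pmin(0.100 + 0.025 * (n - 2), 0.250)
  } else {
    function(n) pmin(0.150 + 0.050 * (n - 2), 0.350)
  }
}

#' Extract labeled AP events and noise segments from a recording
#'
#' Spikes are clustered by the isolation rule: spikes closer than
#' `isolation_s` (default 1 s) belong to the same cluster. A cluster of n
#' spikes becomes an n-AP event if its span fits within the scheduled bin
#' width for n (single spikes need no bin). For each event a snippet of 10
#' pre-frames plus `post_s` seconds is cut; F0 is the mean of the 10 frames
#' before the first AP and the snippet is converted to dF/F0 with that F0.
#' Noise segments are drawn from spans with no spike within `noise_bin_s`.
#'
#' @param spikes a [spike_train()].
#' @param trace fluorescence `ca_trace` (neuropil-corrected raw units).
#' @param schedule bin-width function from [ap_bin_schedule()].
#' @param post_s post-event snippet length, seconds (default 1).
#' @param isolation_s isolation requirement between clusters, seconds.
#' @param noise_bin_s length of the spike-free span defining one noise
#'   segment (default 4).
#' @param max_n_ap clusters larger than this are discarded (default 8).
#' @return `ap_event_set` (see [generate_ap_event_dataset()]) plus
#'   `dropped` (count of clusters discarded by the bin rule or bounds).
#' @export
extract_events <- function(spikes, trace, schedule = ap_bin_schedule(),
                           post_s = 1, isolation_s = 1, noise_bin_s = 4,
                           max_n_ap = 8L) {
  stopifnot(inherits(spikes, "spike_train"), inherits(trace, "ca_trace"))
  times <- spikes$times
  fs <- trace$fs
  f <- trace$samples
  pre <- 10L
  snip_n <- pre + ceiling(post_s * fs)
  dropped <- 0L
  snips <- list(); labels <- integer(0)
  if (length(times)) {
    gaps <- diff(times)
    cl_id <- cumsum(c(1, as.integer(gaps > isolation_s)))
    for (cl in split(times, cl_id)) {
      n <- length(cl)
      ok <- n == 1L || (n <= max_n_ap && (cl[n] - cl[1]) <= schedule(n) + 1e-9)
      if (!ok) { dropped <- dropped + 1L; next }
      i0 <- floor(cl[1] * fs) + 1L
      idx <- (i0 - pre):(i0 + snip_n - pre - 1L)
      if (min(idx) < 1L || max(idx) > length(f)) { dropped <- dropped + 1L; next }
      seg <- f[idx]
      f0 <- mean(seg[seq_len(pre)])
      if (f0 <= 0) { dropped <- dropped + 1L; next }
      snips[[length(snips) + 1L]] <- (seg - f0) / f0
      labels <- c(labels, n)
    }
  }
  # noise segments: non-overlapping snippet windows whose surrounding
  # noise_bin_s span holds no spike
  tt0 <- (0:(length(f) - 1L)) / fs
  pos <- 0
  while (pos + noise_bin_s <= spikes$duration) {
    if (!any(times >= pos & times <= pos + noise_bin_s)) {
      i0 <- floor((pos + noise_bin_s / 2) * fs) + 1L
      idx <- (i0 - pre):(i0 + snip_n - pre - 1L)
      if (min(idx) >= 1L && max(idx) <= length(f)) {
        seg <- f[idx]
        f0 <- mean(seg[seq_len(pre)])
        if (f0 > 0) {
          snips[[length(snips) + 1L]] <- (seg - f0) / f0
          labels <- c(labels, 0L)
        }
      }
      pos <- pos + noise_bin_s
    } else pos <- pos + 1 / fs
  }
  snippets <- if (length(snips)) do.call(rbind, snips)
              else matrix(numeric(0), 0, snip_n)
  structure(list(snippets = snippets, labels = labels, fs = fs,
                 spikes = spikes, recording = trace, pre_frames = pre,
                 dropped = dropped),
            class = "ap_event_set")
}

#' Unit-vector response template
#'
#' Averages the snippets of one event class, subtracts the template mean,
#' and normalizes to unit Euclidean norm.
#'
#' @param snippets matrix (events x frames) or single numeric snippet.
#' @return list: `template` (mean snippet), `unit` (zero-mean unit vector).
#' @export
build_unit_template <- function(snippets) {
  if (is.null(dim(snippets))) snippets <- matrix(snippets, nrow = 1)
  if (nrow(snippets) < 1L) stop("need at least one event")
  template <- colMeans(snippets)
  centered <- template - mean(template)
  nrm <- sqrt(sum(centered^2))
  if (nrm == 0) stop("template is constant; unit vector undefined")
  list(template = template, unit = centered / nrm)
}

#' Project snippets on a unit template
#'
#' Inner product of each raw (un-normalized) snippet with the unit vector.
#'
#' @param snippets matrix (events x frames) or numeric vector.
#' @param unit unit vector from [build_unit_template()].
#' @return numeric scores, one per snippet.
#' @export
project_snippets <- function(snippets, unit) {
  if (is.null(dim(snippets))) snippets <- matrix(snippets, nrow = 1)
  if (ncol(snippets) != length(unit)) stop("length mismatch")
  as.numeric(snippets %*% unit)
}

#' Detection sensitivity index d-prime
#'
#' `(mean_s - mean_n) / sqrt((var_s + var_n) / 2)` with sample variances.
#'
#' @param signal_scores,noise_scores numeric score vectors (>= 2 each).
#' @return scalar d-prime; `Inf` (with warning) when both variances are 0.
#' @export
dprime <- function(signal_scores, noise_scores) {
  if (length(signal_scores) < 2 || length(noise_scores) < 2)
    stop("need at least 2 scores per group")
  pooled <- (stats::var(signal_scores) + stats::var(noise_scores)) / 2
  dm <- mean(signal_scores) - mean(noise_scores)
  if (pooled == 0) {
    warning("zero pooled variance; d-prime infinite")
    return(sign(dm) * Inf)
  }
  dm / sqrt(pooled)
}

#' Empirical ROC curve
#'
#' Sweeps the classification threshold over all placements between sorted
#' unique scores (rule: classify positive when score > threshold), grouping
#' ties, and returns the operating points anchored at (0,0) and (1,1).
#'
#' @param signal_scores,noise_scores numeric score vectors.
#' @return data.frame with columns `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1); attribute `auc` holds the trapezoidal area.
#' @export
roc_curve <- function(signal_scores, noise_scores) {
  if (!length(signal_scores) || !length(noise_scores))
    stop("both score groups must be nonempty")
  thr <- sort(unique(c(signal_scores, noise_scores)), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(noise_scores > t), numeric(1))
  tpr <- vapply(thr, function(t) mean(signal_scores > t), numeric(1))
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  out <- out[!duplicated(out), , drop = FALSE]
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1)
    out <- rbind(out, data.frame(fpr = 1, tpr = 1))
  rownames(out) <- NULL
  attr(out, "auc") <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) +
                                             utils::tail(out$tpr, -1)) / 2)
  out
}

#' Detection accuracy at a fixed false-positive rate
#'
#' The threshold is the empirical `(1 - fpr_target)` quantile of the noise
#' scores using the "higher" order-statistic convention (the
#' `ceiling((1 - fpr) * n)`-th sorted noise score), and the returned
#' accuracy is the fraction of signal scores strictly above it.
#'
#' @param signal_scores,noise_scores numeric score vectors.
#' @param fpr_target target false-positive rate in (0, 1) (default 0.05).
#' @return list: `tpr`, `threshold`, `fpr_achieved`.
#' @export
accuracy_at_fpr <- function(signal_scores, noise_scores, fpr_target = 0.05) {
  stopifnot(fpr_target > 0, fpr_target < 1)
  n <- length(noise_scores)
  if (n < 1 / fpr_target)
    warning(sprintf(
      "only %d noise scores for fpr %.3g; using conservative quantile",
      n, fpr_target))
  kth <- min(n, max(1L, ceiling((1 - fpr_target) * n)))
  thr <- sort(noise_scores)[kth]
  list(tpr = mean(signal_scores > thr), threshold = thr,
       fpr_achieved = mean(noise_scores > thr))
}

#' Full detection analysis of an AP event set
#'
#' Builds per-class unit templates, projects every event and noise snippet
#' on each class template, and reports d-prime, the ROC curve, and accuracy
#' at the target false-positive rate per AP class.
#'
#' @param events an `ap_event_set`.
#' @param fpr_target false-positive rate for the accuracy summary.
#' @param common_template if TRUE, use the 1-AP template for every class
#'   instead of per-class templates.
#' @return list of class `detection_result`: `per_class` (data.frame with
#'   n_ap, n_events, dprime, accuracy, auc), `roc` (named list of ROC
#'   data.frames), `templates`, `scores`.
#' @export
detect_analysis <- function(events, fpr_target = 0.05,
                            common_template = FALSE) {
  stopifnot(inherits(events, "ap_event_set"))
  lab <- events$labels
  classes <- sort(unique(lab[lab > 0]))
  if (!length(classes)) stop("event set holds no AP events")
  if (!any(lab == 0)) stop("event set holds no noise segments")
  noise_snips <- events$snippets[lab == 0, , drop = FALSE]
  templates <- list(); rocs <- list(); scores <- list()
  per <- data.frame()
  base_cls <- classes[1]
  for (nc in classes) {
    tmpl_src <- if (common_template) base_cls else nc
    tm <- build_unit_template(events$snippets[lab == tmpl_src, ,
                                              drop = FALSE])
    templates[[as.character(nc)]] <- tm
    s_sig <- project_snippets(events$snippets[lab == nc, , drop = FALSE],
                              tm$unit)
    s_noise <- project_snippets(noise_snips, tm$unit)
    roc <- roc_curve(s_sig, s_noise)
    acc <- accuracy_at_fpr(s_sig, s_noise, fpr_target)
    rocs[[as.character(nc)]] <- roc
    scores[[as.character(nc)]] <- list(signal = s_sig, noise = s_noise)
    per <- rbind(per, data.frame(n_ap = nc, n_events = length(s_sig),
                                 dprime = dprime(s_sig, s_noise),
                                 accuracy = acc$tpr,
                                 auc = attr(roc, "auc")))
  }
  structure(list(per_class = per, roc = rocs, templates = templates,
                 scores = scores, fpr_target = fpr_target),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> accuracy at FPR = %.2g:\n", x$fpr_target))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
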