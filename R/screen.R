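#' Per-cell response metrics for a screen plate
#'
#' For every cell and AP-train count: peak dF/F0 (maximum of the dF/F0 trace
#' inside the response window after train onset), SNR (fluorescence peak
#' above baseline divided by the pre-stimulus signal standard deviation),
#' and for the 10-AP train the half-decay time via [half_decay_time()].
#'
#' @param plate tidy plate data.frame from [generate_screen_plate()] (or the
#'   same columns read from CSV: well, variant, cell_id, train_aps, frame,
#'   time_s, f), with `pre_s`/`fs` attributes or supplied explicitly.
#' @param pre_s baseline duration before train onset, seconds.
#' @param fs frame rate, frames/s.
#' @param response_window_s length of the post-onset window searched for the
#'   peak; `Inf` (default) uses the rest of the trace.
#' @param decay_train_aps AP count whose response gets a half-decay estimate
#'   (default 10).
#' @return data.frame per (cell, train): well, variant, cell_id, train_aps,
#'   peak_dff, snr, half_decay_s (NA except for `decay_train_aps`).
#' @export
well_metrics <- function(plate, pre_s = attr(plate, "pre_s"),
                         fs = attr(plate, "fs"),
                         response_window_s = Inf, decay_train_aps = 10) {
  stopifnot(!is.null(pre_s), !is.null(fs))
  if (pre_s * fs < 10) stop("pre-stimulus window must hold >= 10 frames")
  key <- interaction(plate$well, plate$cell_id, plate$train_aps, drop = TRUE)
  out <- lapply(split(plate, key), function(d) {
    d <- d[order(d$frame), ]
    tr <- ca_trace(d$f, fs)
    base_idx <- window_idx(tr, 0, pre_s - 0.5 / fs)
    f0 <- mean(d$f[base_idx])
    base_sd <- stats::sd(d$f[base_idx])
    dff <- compute_dff(tr, f0)
    w_end <- min(pre_s + response_window_s, max(trace_times(tr)))
    resp_idx <- window_idx(tr, pre_s, w_end)
    peak <- max(dff$samples[resp_idx])
    snr <- if (base_sd == 0) Inf else (peak * f0) / base_sd
    hd <- NA_real_
    if (!is.na(decay_train_aps) && d$train_aps[1] == decay_train_aps) {
      hd <- half_decay_time(dff, peak_time = pre_s)$half_decay_s
    }
    data.frame(well = d$well[1], variant = d$variant[1],
               cell_id = d$cell_id[1], train_aps = d$train_aps[1],
               peak_dff = peak, snr = snr, half_decay_s = hd)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$well, out$cell_id, out$train_aps), ]
  rownames(out) <- NULL
  out
}

#' Compare a variant to its parent indicator at one AP count
#'
#' Fold-change of median peak dF/F0 and a two-sided Wilcoxon rank-sum test
#' on the per-cell peaks.
#'
#' @param variant_peaks,parent_peaks per-cell peak dF/F0 vectors (>= 3
#'   cells each).
#' @return list: `fold_change` (NA and `flagged = TRUE` when the parent
#'   median is not positive), `p_ranksum`, `n`.
#' @export
compare_variant_to_parent <- function(variant_peaks, parent_peaks) {
  if (length(variant_peaks) < 3 || length(parent_peaks) < 3)
    stop("need at least 3 cells per side")
  med_p <- stats::median(parent_peaks)
  fold <- if (med_p <= 0) NA_real_ else stats::median(variant_peaks) / med_p
  p <- stats::wilcox.test(variant_peaks, parent_peaks, exact = FALSE)$p.value
  list(fold_change = fold, p_ranksum = p, flagged = med_p <= 0,
       n = c(variant = length(variant_peaks), parent = length(parent_peaks)))
}

#' Rank screen variants against a parent indicator
#'
#' Applies the screen selection rule: a variant is excluded if it shows a
#' significant reduction of the maximal (160-AP) response; surviving
#' variants are ranked by the number of significant amplitude improvements
#' over the parent at the sentinel train counts (1, 3, 10 APs), breaking
#' ties by mean fold-change at those counts.
#'
#' @param metrics per-cell metrics table from [well_metrics()] covering the
#'   parent and all variants.
#' @param parent variant label of the parent indicator.
#' @param improve_aps AP counts scored for improvement (default c(1, 3, 10)).
#' @param max_ap AP count defining the maximal response (default 160).
#' @param alpha significance level for both rules (default 0.01).
#' @return data.frame, one row per non-parent variant, ordered best first:
#'   variant, n_improved, mean_fold, excluded, plus per-AP fold/p columns.
#' @export
rank_variants <- function(metrics, parent, improve_aps = c(1, 3, 10),
                          max_ap = 160, alpha = 0.01) {
  stopifnot(parent %in% metrics$variant)
  variants <- setdiff(unique(metrics$variant), parent)
  peaks <- function(v, nap)
    metrics$peak_dff[metrics$variant == v & metrics$train_aps == nap]
  rows <- lapply(variants, function(v) {
    folds <- numeric(0); ps <- numeric(0)
    for (nap in improve_aps) {
      cmp <- compare_variant_to_parent(peaks(v, nap), peaks(parent, nap))
      folds <- c(folds, cmp$fold_change); ps <- c(ps, cmp$p_ranksum)
    }
    excluded <- FALSE
    if (max_ap %in% metrics$train_aps) {
      cmx <- compare_variant_to_parent(peaks(v, max_ap), peaks(parent, max_ap))
      excluded <- !is.na(cmx$fold_change) && cmx$fold_change < 1 &&
        cmx$p_ranksum < alpha
    }
    n_imp <- sum(ps < alpha & folds > 1, na.rm = TRUE)
    row <- data.frame(variant = v, n_improved = n_imp,
                      mean_fold = mean(folds, na.rm = TRUE),
                      excluded = excluded)
    for (i in seq_along(improve_aps)) {
      row[[paste0("fold_", improve_aps[i], "ap")]] <- folds[i]
      row[[paste0("p_", improve_aps[i], "ap")]] <- ps[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$excluded, -out$n_improved, -out$mean_fold), ]
  rownames(out) <- NULL
  out
}
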