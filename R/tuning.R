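#' Build a per-cell trial table of stimulus and blank responses
#'
#' For one cell, computes the mean dF/F0 over each 4 s stimulus period and
#' each preceding blank period, arranged as directions x trials matrices.
#' The dF/F0 of each trial uses an F0 averaged over the 1 s immediately
#' before grating onset of that trial.
#'
#' @param trace corrected fluorescence `ca_trace` (raw units; per-trial
#'   dF/F0 is computed internally), or a dF/F0 trace with `already_dff =
#'   TRUE`.
#' @param schedule stimulus schedule data.frame from [stimulus_schedule()].
#' @param already_dff if TRUE, `trace` is already dF/F0 and no per-trial
#'   renormalization is applied.
#' @param f0_window_s length of the pre-stimulus F0 window, seconds.
#' @return object of class `trial_table`: `stim` and `blank` matrices
#'   (directions x trials), `directions`, `n_trials`.
#' @export
build_trial_table <- function(trace, schedule, already_dff = FALSE,
                              f0_window_s = 1) {
  stopifnot(inherits(trace, "ca_trace"), is.data.frame(schedule))
  need <- c("trial", "direction", "blank_start", "stim_start", "stim_end")
  if (!all(need %in% names(schedule))) stop("schedule is missing columns")
  if (anyNA(schedule)) stop("schedule contains missing trials")
  tmax <- max(trace_times(trace))
  if (max(schedule$stim_end) > tmax + 1 / trace$fs + 1e-9)
    stop("schedule extends past the end of the trace")
  dirs <- sort(unique(schedule$direction))
  n_rep <- nrow(schedule) / length(dirs)
  if (n_rep != round(n_rep)) stop("unbalanced schedule")
  stim <- matrix(NA_real_, length(dirs), n_rep,
                 dimnames = list(as.character(dirs), NULL))
  blank <- stim
  rep_count <- setNames(integer(length(dirs)), as.character(dirs))
  for (i in seq_len(nrow(schedule))) {
    dlab <- as.character(schedule$direction[i])
    rep_count[dlab] <- rep_count[dlab] + 1L
    half <- 0.5 / trace$fs  # half-frame shrink keeps window ends exclusive
    if (already_dff) {
      seg_s <- trace$samples[window_idx(trace, schedule$stim_start[i],
                                        schedule$stim_end[i] - half)]
      seg_b <- trace$samples[window_idx(trace, schedule$blank_start[i],
                                        schedule$stim_start[i] - half)]
      stim[dlab, rep_count[dlab]] <- mean(seg_s)
      blank[dlab, rep_count[dlab]] <- mean(seg_b)
    } else {
      f0 <- compute_f0(trace, c(schedule$stim_start[i] - f0_window_s,
                                schedule$stim_start[i] - half))
      dff <- compute_dff(trace, f0)
      seg_s <- dff$samples[window_idx(trace, schedule$stim_start[i],
                                      schedule$stim_end[i] - half)]
      seg_b <- dff$samples[window_idx(trace, schedule$blank_start[i],
                                      schedule$stim_start[i] - half)]
      stim[dlab, rep_count[dlab]] <- mean(seg_s)
      blank[dlab, rep_count[dlab]] <- mean(seg_b)
    }
  }
  if (anyNA(stim) || anyNA(blank)) stop("schedule/trace misalignment")
  structure(list(stim = stim, blank = blank, directions = dirs,
                 n_trials = n_rep),
            class = "trial_table")
}

#' Construct a trial table directly from response matrices
#'
#' Mainly for programmatic use (simulation studies on the classifier) when
#' the per-trial means are already available.
#'
#' @param stim directions x trials matrix of stimulus-period mean dF/F0,
#'   with direction labels as rownames.
#' @param blank matching matrix of blank-period means.
#' @return a `trial_table`.
#' @export
trial_table <- function(stim, blank) {
  stopifnot(is.matrix(stim), is.matrix(blank), all(dim(stim) == dim(blank)))
  dirs <- as.numeric(rownames(stim))
  if (anyNA(dirs)) stop("stim must have numeric direction rownames")
  structure(list(stim = stim, blank = blank, directions = dirs,
                 n_trials = ncol(stim)),
            class = "trial_table")
}

#' Classify a cell as visually responsive
#'
#' A cell is responsive if (1) its trial-averaged stimulus-period dF/F0
#' exceeds `dff_min` for at least one direction, and (2) a one-way ANOVA
#' across nine groups -- blank plus the eight directions, one observation per
#' trial repetition -- rejects at `alpha`. Blank observations are the mean
#' blank response within each repetition cycle, giving the same number of
#' observations per group.
#'
#' @param table a `trial_table`.
#' @param dff_min minimum trial-averaged response (default 0.05).
#' @param alpha ANOVA level (default 0.01).
#' @return list: `responsive` (logical), `p_anova`, `max_response`.
#' @export
classify_responsive <- function(table, dff_min = 0.05, alpha = 0.01) {
  stopifnot(inherits(table, "trial_table"))
  if (table$n_trials < 2) stop("need at least 2 trials per direction")
  blank_obs <- colMeans(table$blank)
  vals <- c(blank_obs, as.vector(t(table$stim)))
  grp <- factor(rep(c("blank", rownames(table$stim)),
                    each = table$n_trials),
                levels = c("blank", rownames(table$stim)))
  gm <- tapply(vals, grp, mean)
  within_ss <- sum((vals - gm[grp])^2)
  p <- if (within_ss == 0) {
    # degenerate noiseless input: reject iff group means differ at all
    if (stats::var(gm) > 0) 0 else 1
  } else {
    stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
  }
  max_resp <- max(rowMeans(table$stim))
  list(responsive = is.finite(p) && p < alpha && max_resp > dff_min,
       p_anova = p, max_response = max_resp)
}

#' Preferred stimulus direction
#'
#' The direction whose trial-averaged response is greatest; ties are broken
#' toward the lowest direction label.
#'
#' @param table a `trial_table`.
#' @return direction in degrees.
#' @export
preferred_stimulus <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  m <- rowMeans(table$stim)
  table$directions[which.max(m)]  # which.max takes the first (lowest label)
}

# Model curve for the double-Gaussian fit.
dg_model <- function(theta, par, delta_deg) {
  par[["b"]] +
    par[["a1"]] * exp(-circ_dist_deg(theta, par[["theta_pref"]])^2 /
                        (2 * par[["sigma"]]^2)) +
    par[["a2"]] * exp(-circ_dist_deg(theta, par[["theta_pref"]] + delta_deg)^2 /
                        (2 * par[["sigma"]]^2))
}

#' Fit a double-Gaussian orientation/direction tuning curve
#'
#' Least-squares fit of `B + A1 G(theta; theta_pref, sigma) + A2 G(theta;
#' theta_pref + delta, sigma)` to the 8-point trial-averaged tuning curve,
#' where G is a Gaussian in minimal circular distance. `delta = 180` treats
#' the two lobes as opposite drift directions (default); `delta = 90` places
#' the second lobe at the orthogonal orientation. Multi-start L-BFGS-B
#' (4 starts) with bounds sigma in [5, 180] degrees and amplitudes >= 0;
#' theta_pref is initialized at [preferred_stimulus()].
#'
#' @param table a `trial_table`.
#' @param delta_deg angular offset of the second Gaussian (180 or 90).
#' @return object of class `tuning_fit`: theta_pref, sigma, a1, a2, b, osi,
#'   sse, degenerate flag, converged flag, delta_deg.
#' @export
fit_tuning <- function(table, delta_deg = 180) {
  stopifnot(inherits(table, "trial_table"))
  y <- rowMeans(table$stim)
  th <- table$directions
  rng <- max(y) - min(y)
  sse_fun <- function(p) {
    pr <- c(theta_pref = p[1], sigma = p[2], a1 = p[3], a2 = p[4], b = p[5])
    sum((y - dg_model(th, pr, delta_deg))^2)
  }
  th0 <- preferred_stimulus(table)
  starts <- list(c(th0, 30, rng, rng / 4, min(y)),
                 c(th0, 60, rng, rng / 4, min(y)),
                 c((th0 + 45) %% 360, 30, rng, rng / 2, min(y)),
                 c(th0, 20, rng / 2, rng / 2, mean(y)))
  lower <- c(-360, 5, 0, 0, -Inf)
  upper <- c(720, 180, Inf, Inf, Inf)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, sse_fun, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(structure(list(theta_pref = NA_real_, sigma = NA_real_,
                          a1 = NA_real_, a2 = NA_real_, b = NA_real_,
                          osi = NA_real_, sse = NA_real_, degenerate = TRUE,
                          converged = FALSE, delta_deg = delta_deg),
                     class = "tuning_fit"))
  p <- best$par
  out <- structure(list(theta_pref = p[1] %% 360, sigma = p[2], a1 = p[3],
                        a2 = p[4], b = p[5], osi = NA_real_,
                        sse = best$value,
                        degenerate = (p[3] < 1e-3 * max(abs(rng), 1e-12) &&
                                        p[4] < 1e-3 * max(abs(rng), 1e-12)) ||
                          rng == 0,
                        converged = best$convergence == 0,
                        delta_deg = delta_deg),
                   class = "tuning_fit")
  out$osi <- compute_osi(out)
  out
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "<tuning_fit> theta_pref = %.1f deg, sigma = %.1f deg, A1 = %.3g, A2 = %.3g, B = %.3g, OSI = %.3f%s\n",
    x$theta_pref, x$sigma, x$a1, x$a2, x$b, x$osi,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Orientation selectivity index from a tuning fit
#'
#' `OSI = (R_pref - R_ortho) / (R_pref + R_ortho)` where `R_pref` and
#' `R_ortho` are the fitted responses at the preferred direction and at the
#' orthogonal orientation (`theta_pref + 90` degrees).
#'
#' @param fit a `tuning_fit`, or a list with fields theta_pref, sigma, a1,
#'   a2, b (and optionally delta_deg).
#' @return scalar OSI; `NA` (with a warning) if `R_pref + R_ortho <= 0`.
#' @export
compute_osi <- function(fit) {
  dd <- if (!is.null(fit$delta_deg)) fit$delta_deg else 180
  pr <- c(theta_pref = fit$theta_pref, sigma = fit$sigma, a1 = fit$a1,
          a2 = fit$a2, b = fit$b)
  if (anyNA(pr)) return(NA_real_)
  r_pref <- dg_model(fit$theta_pref, pr, dd)
  r_ortho <- dg_model(fit$theta_pref + 90, pr, dd)
  if (r_pref + r_ortho <= 0) {
    warning("R_pref + R_ortho <= 0; OSI undefined")
    return(NA_real_)
  }
  (r_pref - r_ortho) / (r_pref + r_ortho)
}

#' Population tuning summary
#'
#' Convenience wrapper: builds trial tables for every cell of a generated
#' population (after neuropil correction), classifies responsiveness, and
#' fits tuning for responsive cells.
#'
#' @param pop output of [generate_tuned_population()].
#' @param r neuropil coefficient used for correction.
#' @param delta_deg second-lobe offset for the tuning fit.
#' @param dff_min,alpha responsiveness thresholds.
#' @return data.frame per cell: cell_id, responsive, p_anova, theta_pref,
#'   sigma, a1, a2, b, osi.
#' @export
analyze_population_tuning <- function(pop, r = 0.7, delta_deg = 180,
                                      dff_min = 0.05, alpha = 0.01) {
  out <- lapply(pop$recordings, function(rec) {
    corr <- neuropil_correct(rec$f_meas, rec$f_np, r)
    tab <- build_trial_table(corr, pop$schedule)
    cls <- classify_responsive(tab, dff_min, alpha)
    row <- data.frame(cell_id = rec$cell_id, responsive = cls$responsive,
                      p_anova = cls$p_anova, theta_pref = NA_real_,
                      sigma = NA_real_, a1 = NA_real_, a2 = NA_real_,
                      b = NA_real_, osi = NA_real_)
    if (cls$responsive) {
      fit <- fit_tuning(tab, delta_deg)
      row$theta_pref <- fit$theta_pref; row$sigma <- fit$sigma
      row$a1 <- fit$a1; row$a2 <- fit$a2; row$b <- fit$b; row$osi <- fit$osi
    }
    row
  })
  do.call(rbind, out)
}
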