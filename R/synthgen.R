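#' Imaging configuration for the forward model
#'
#' @param fs frame rate, frames/s.
#' @param f0 baseline fluorescence, arbitrary units (> 0).
#' @param noise_sd white-noise standard deviation as a fraction of `f0`.
#' @param r_true neuropil contamination coefficient actually mixed into the
#'   measured signal, in `[0, 1)`.
#' @param neuropil_amp standard deviation of the shared slow neuropil
#'   fluctuation, as a fraction of `f0`.
#' @param seed integer seed; all generators are reproducible from it.
#' @return list of class `imaging_config`.
#' @export
imaging_config <- function(fs = 15, f0 = 100, noise_sd = 0.02,
                           r_true = 0.7, neuropil_amp = 0.05, seed = 1L) {
  stopifnot(fs > 0, f0 > 0, noise_sd >= 0, r_true >= 0, r_true < 1,
            neuropil_amp >= 0)
  structure(list(fs = fs, f0 = f0, noise_sd = noise_sd, r_true = r_true,
                 neuropil_amp = neuropil_amp, seed = as.integer(seed)),
            class = "imaging_config")
}

#' Spike train container
#'
#' @param times spike times in seconds.
#' @param duration recording duration in seconds.
#' @return list of class `spike_train` with sorted, deduplicated times.
#' @export
spike_train <- function(times, duration) {
  times <- sort(unique(as.numeric(times)))
  stopifnot(duration > 0)
  if (length(times) && (min(times) < 0 || max(times) > duration))
    stop("spike times must lie in [0, duration]")
  structure(list(times = times, duration = duration), class = "spike_train")
}

# Group sorted spike times into bursts by chaining: spikes whose
# inter-spike gap is at most `window_s` belong to the same burst, so a
# contiguous high-frequency train forms a single saturating burst.
# Returns data.frame(t0 = burst onset, n = AP count).
group_bursts <- function(times, window_s = 0.25) {
  if (!length(times)) return(data.frame(t0 = numeric(0), n = integer(0)))
  brk <- c(1L, cumsum(diff(times) > window_s + 1e-12) + 1L)
  t0 <- tapply(times, brk, min)
  n <- tapply(times, brk, length)
  data.frame(t0 = as.numeric(t0), n = as.integer(n))
}

#' Render a spike train as a noiseless dF/F0 series
#'
#' Spikes are grouped into bursts by chaining: consecutive spikes separated
#' by at most `burst_window_s` share a burst, so contiguous trains saturate
#' as a whole; each burst contributes the difference-of-exponentials kernel
#' scaled so its peak equals `k$amplitude_curve(n)` for an n-AP burst, and
#' bursts superpose additively. This models per-burst saturation: the
#' amplitude curve, not per-spike summation, sets multi-AP peaks.
#'
#' @param spikes a [spike_train()].
#' @param k an [indicator_kinetics()].
#' @param fs sampling rate, frames/s.
#' @param burst_window_s burst grouping window, seconds (default 0.25).
#' @return `ca_trace` of length `ceiling(duration * fs)` in dF/F0 units.
#' @export
spikes_to_dff <- function(spikes, k, fs, burst_window_s = 0.25) {
  stopifnot(inherits(spikes, "spike_train"), inherits(k, "indicator_kinetics"),
            fs > 0)
  nfr <- ceiling(spikes$duration * fs)
  tt <- (seq_len(nfr) - 1L) / fs
  out <- numeric(nfr)
  bursts <- group_bursts(spikes$times, burst_window_s)
  if (nrow(bursts)) {
    anchor <- if (is.null(k$decay_anchor)) "burst" else k$decay_anchor
    taus <- solve_kernel_taus(k$half_rise_s, k$half_decay_s, anchor)
    h <- transient_kernel_fn(taus[["tau_r"]], taus[["tau_d"]])
    hp <- h(kernel_peak_time(taus[["tau_r"]], taus[["tau_d"]]))
    for (b in seq_len(nrow(bursts))) {
      amp <- k$amplitude_curve(bursts$n[b])
      out <- out + (amp / hp) * h(tt - bursts$t0[b])
    }
  }
  ca_trace(out, fs)
}

# Smooth zero-mean unit-sd Gaussian-process sample with ~corr_s correlation
# length: white noise convolved with a Gaussian window.
smooth_gp <- function(n, fs, corr_s = 1) {
  w <- stats::rnorm(n + 1L)  # +1 guards n = 0 edge
  half <- max(1L, ceiling(3 * corr_s * fs))
  kk <- stats::dnorm(seq(-half, half) / fs, sd = corr_s)
  sm <- stats::filter(c(rev(w[seq_len(half)]), w, w[seq_len(half)]),
                      kk / sum(kk), circular = TRUE)
  sm <- as.numeric(sm)[half + seq_len(n)]
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) rep(0, n) else (sm - mean(sm)) / s
}

#' Render a dF/F0 series into measured cell and neuropil fluorescence
#'
#' Generative inverse of the neuropil correction: the neuropil channel is
#' baseline fluorescence plus a slow shared fluctuation, the true cell signal
#' is `f0 * (1 + dff)` plus white imaging noise, and the measured cell signal
#' is contaminated by `r_true` times the neuropil channel.
#'
#' @param dff `ca_trace` (dF/F0 units) from [spikes_to_dff()].
#' @param cfg an [imaging_config()]; `cfg$seed` makes output reproducible.
#' @param use_seed set the RNG from `cfg$seed` (default TRUE); callers
#'   managing their own RNG stream pass FALSE.
#' @return list with `f_meas` and `f_np` traces (`ca_trace`).
#' @export
render_fov <- function(dff, cfg, use_seed = TRUE) {
  stopifnot(inherits(dff, "ca_trace"), inherits(cfg, "imaging_config"))
  if (use_seed) set.seed(cfg$seed)
  n <- length(dff$samples)
  fluct <- if (cfg$neuropil_amp > 0)
    cfg$neuropil_amp * smooth_gp(n, dff$fs, corr_s = 1) else numeric(n)
  f_np <- cfg$f0 * (1 + fluct)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd * cfg$f0)
           else numeric(n)
  f_true <- cfg$f0 * (1 + dff$samples) + noise
  f_meas <- f_true + cfg$r_true * f_np
  list(f_meas = ca_trace(f_meas, dff$fs, dff$t0),
       f_np = ca_trace(f_np, dff$fs, dff$t0))
}

# --- visual-stimulation population ----------------------------------------

# Wrapped circular distance in degrees on [0, 360).
circ_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Double-Gaussian direction-tuning rate profile (spikes/s).
tuning_rate <- function(theta, theta_pref, sigma, a1, a2, b,
                        delta_deg = 180) {
  b + a1 * exp(-circ_dist_deg(theta, theta_pref)^2 / (2 * sigma^2)) +
    a2 * exp(-circ_dist_deg(theta, theta_pref + delta_deg)^2 / (2 * sigma^2))
}

#' Default stimulus schedule: 8 directions x 5 trials, 4 s blank + 4 s grating
#'
#' @param n_trials_per_dir trials per direction (default 5).
#' @param blank_s,stim_s blank and stimulus durations, seconds.
#' @return data.frame with columns trial, rep, direction, blank_start,
#'   stim_start, stim_end.
#' @export
stimulus_schedule <- function(n_trials_per_dir = 5, blank_s = 4, stim_s = 4) {
  dirs <- seq(0, 315, by = 45)
  trial <- seq_len(8L * n_trials_per_dir)
  rep_id <- rep(seq_len(n_trials_per_dir), each = 8L)
  direction <- rep(dirs, times = n_trials_per_dir)
  blank_start <- (trial - 1L) * (blank_s + stim_s)
  data.frame(trial = trial, rep = rep_id, direction = direction,
             blank_start = blank_start, stim_start = blank_start + blank_s,
             stim_end = blank_start + blank_s + stim_s)
}

#' Generate a trial-structured, orientation-tuned synthetic population
#'
#' Each cell receives the standard schedule (8 drifting-grating directions
#' separated by 45 degrees, 5 trials each, 4 s blank + 4 s stimulus).
#' Responsive cells fire inhomogeneous-Poisson spikes whose stimulus-period
#' rate follows a double-Gaussian direction-tuning profile; non-responsive
#' cells fire homogeneous background spikes. Spikes are rendered to
#' fluorescence with [spikes_to_dff()] and [render_fov()].
#'
#' @param n_cells number of cells.
#' @param frac_responsive fraction of tuned, stimulus-driven cells; the first
#'   `round(n_cells * frac_responsive)` cells are responsive.
#' @param k an [indicator_kinetics()].
#' @param cfg an [imaging_config()].
#' @param tuning_params list overriding defaults: `a1` (peak rate, Hz), `a2`
#'   (opposite-direction amplitude), `b` (background rate), `sigma_deg`
#'   (tuning width), `delta_deg` (angular offset of the second lobe, 180 for
#'   direction tuning).
#' @param schedule stimulus schedule, see [stimulus_schedule()].
#' @return list with `recordings` (per cell: `f_meas`, `f_np`, `spikes`) ,
#'   `schedule`, and `truth` (data.frame of per-cell ground truth).
#' @export
generate_tuned_population <- function(n_cells, frac_responsive, k, cfg,
                                      tuning_params = list(),
                                      schedule = stimulus_schedule()) {
  stopifnot(frac_responsive >= 0, frac_responsive <= 1)
  tp <- utils::modifyList(list(a1 = 8, a2 = 2, b = 0.3, sigma_deg = 30,
                               delta_deg = 180), tuning_params)
  set.seed(cfg$seed)
  dur <- max(schedule$stim_end)
  n_resp <- round(n_cells * frac_responsive)
  recordings <- vector("list", n_cells)
  truth <- data.frame(cell_id = seq_len(n_cells),
                      responsive = seq_len(n_cells) <= n_resp,
                      theta_pref = stats::runif(n_cells, 0, 360),
                      sigma = tp$sigma_deg, a1 = tp$a1, a2 = tp$a2, b = tp$b)
  truth$osi_true <- with(truth, {
    rp <- tuning_rate(theta_pref, theta_pref, sigma, a1, a2, b, tp$delta_deg)
    ro <- tuning_rate(theta_pref + 90, theta_pref, sigma, a1, a2, b,
                      tp$delta_deg)
    (rp - ro) / (rp + ro)
  })
  for (i in seq_len(n_cells)) {
    times <- numeric(0)
    # background spikes throughout
    nb <- stats::rpois(1, tp$b * dur)
    if (nb) times <- stats::runif(nb, 0, dur)
    if (truth$responsive[i]) {
      for (tr in seq_len(nrow(schedule))) {
        rate <- tuning_rate(schedule$direction[tr], truth$theta_pref[i],
                            tp$sigma_deg, tp$a1, tp$a2, 0, tp$delta_deg)
        ns <- stats::rpois(1, rate * (schedule$stim_end[tr] -
                                        schedule$stim_start[tr]))
        if (ns) times <- c(times, stats::runif(ns, schedule$stim_start[tr],
                                               schedule$stim_end[tr]))
      }
    }
    st <- spike_train(times, dur)
    dff <- spikes_to_dff(st, k, cfg$fs)
    fov <- render_fov(dff, cfg, use_seed = FALSE)
    recordings[[i]] <- list(cell_id = i, f_meas = fov$f_meas,
                            f_np = fov$f_np, spikes = st)
  }
  list(recordings = recordings, schedule = schedule, truth = truth)
}

# --- AP-event dataset ------------------------------------------------------

#' Generate labeled n-AP event snippets and no-AP noise segments
#'
#' Builds a long recording in which isolated n-AP bursts (inter-event spacing
#' well over 1 s) are placed sequentially, renders it at the configured noise
#' level, and cuts labeled snippets: 10 pre-event frames (used for the
#' event-local F0) plus `post_s` seconds. Noise segments of the same length
#' are cut from a spike-free span.
#'
#' @param counts_per_class named integer vector, e.g. `c("1" = 199, "2" = 70)`,
#'   mapping burst AP count to number of events.
#' @param n_noise number of no-AP noise segments.
#' @param k an [indicator_kinetics()].
#' @param cfg an [imaging_config()].
#' @param post_s post-event snippet length, seconds.
#' @param spacing_s distance between consecutive planted events, seconds
#'   (must exceed 1 s isolation plus snippet length; default 6).
#' @return list of class `ap_event_set`: `snippets` (matrix, events x frames,
#'   dF/F0), `labels` (integer AP counts, 0 = noise), `fs`, `spikes`
#'   (the full planted [spike_train()]), `recording` (the rendered `f_meas`
#'   trace), `pre_frames`.
#' @export
generate_ap_event_dataset <- function(counts_per_class, n_noise, k, cfg,
                                      post_s = 1, spacing_s = 6) {
  stopifnot(all(counts_per_class >= 0), n_noise >= 0, spacing_s > 2 + post_s)
  ncl <- as.integer(names(counts_per_class))
  stopifnot(!anyNA(ncl), all(ncl >= 1))
  set.seed(cfg$seed)
  n_events <- sum(counts_per_class)
  # event block first, then a spike-free tail for noise segments
  snip_len_s <- 10 / cfg$fs + post_s
  noise_span <- n_noise * snip_len_s + 4
  dur <- spacing_s * (n_events + 1) + noise_span
  labels_ev <- rep(ncl, times = counts_per_class)
  labels_ev <- sample(labels_ev)  # interleave classes
  times <- numeric(0)
  ev_t0 <- numeric(n_events)
  for (i in seq_len(n_events)) {
    t0 <- spacing_s * i
    n <- labels_ev[i]
    # n APs spread within the class bin width (250 ms window cap)
    tt <- if (n == 1) t0 else t0 + seq(0, 0.95 * min(0.25, 0.025 * n),
                                       length.out = n)
    times <- c(times, tt)
    ev_t0[i] <- t0
  }
  st <- spike_train(times, dur)
  dff <- spikes_to_dff(st, k, cfg$fs)
  fov <- render_fov(dff, cfg, use_seed = FALSE)
  f <- fov$f_meas$samples
  pre <- 10L
  snip_n <- pre + ceiling(post_s * cfg$fs)
  cut_snip <- function(onset_s) {
    i0 <- floor(onset_s * cfg$fs) + 1L  # first frame at/after onset
    idx <- (i0 - pre):(i0 + snip_n - pre - 1L)
    if (min(idx) < 1L || max(idx) > length(f)) return(NULL)
    seg <- f[idx]
    f0 <- mean(seg[seq_len(pre)])
    (seg - f0) / f0
  }
  snippets <- t(vapply(ev_t0, cut_snip, numeric(snip_n)))
  labels <- labels_ev
  if (n_noise > 0) {
    base <- spacing_s * (n_events + 1) + 2
    for (j in seq_len(n_noise)) {
      s <- cut_snip(base + (j - 1) * snip_len_s)
      snippets <- rbind(snippets, s)
      labels <- c(labels, 0L)
    }
  }
  rownames(snippets) <- NULL
  structure(list(snippets = snippets, labels = as.integer(labels),
                 fs = cfg$fs, spikes = st, recording = fov$f_meas,
                 pre_frames = pre),
            class = "ap_event_set")
}

# --- depth profiles --------------------------------------------------------

#' Generate synthetic depth-attenuation profiles
#'
#' Per dendrite, fluorescence decays exponentially with imaging depth:
#' `F(z) = F(z0) * exp(-(z - z0)/lambda) * (1 + eps)`, with multiplicative
#' Gaussian noise `eps ~ N(0, cv)` truncated so fluorescence stays positive.
#'
#' @param n_dendrites number of dendrites.
#' @param lambda_true attenuation length constant, micrometres (finite, > 0).
#' @param depth_grid increasing nonnegative depths, micrometres.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @param f_surface fluorescence at the shallowest depth (arbitrary units).
#' @return data.frame columns dendrite_id, depth_um, fluor.
#' @export
generate_depth_profiles <- function(n_dendrites, lambda_true, depth_grid,
                                    noise_cv = 0.1, seed = 1L,
                                    f_surface = 1000) {
  if (!is.finite(lambda_true) || lambda_true <= 0)
    stop("`lambda_true` must be finite and positive")
  stopifnot(all(depth_grid >= 0), all(diff(depth_grid) > 0),
            noise_cv >= 0)
  set.seed(seed)
  z0 <- depth_grid[1]
  out <- do.call(rbind, lapply(seq_len(n_dendrites), function(d) {
    mu <- f_surface * exp(-(depth_grid - z0) / lambda_true)
    eps <- stats::rnorm(length(mu), 0, noise_cv)
    f <- pmax(mu * (1 + eps), 1e-6 * f_surface)
    data.frame(dendrite_id = d, depth_um = depth_grid, fluor = f)
  }))
  rownames(out) <- NULL
  out
}

# --- culture-screen plate --------------------------------------------------

#' Generate a synthetic culture-screen plate
#'
#' One well per indicator variant; each well holds `n_cells_per_well` cells,
#' each stimulated with every AP train in the protocol (field stimulation at
#' `train_hz`). Per-cell kinetics are jittered around the variant parameters
#' with lognormal multiplicative jitter (CV `amp_jitter_cv` on amplitude,
#' `tau_jitter_cv` on half-times).
#'
#' @param variants named list of [indicator_kinetics()] objects (names become
#'   variant labels).
#' @param cfg an [imaging_config()]; the screen default frame rate is 35 Hz.
#' @param protocol integer AP counts per train.
#' @param n_cells_per_well cells per well.
#' @param train_hz within-train AP rate, Hz.
#' @param pre_s,post_s baseline before and recording after train onset, s.
#' @param amp_jitter_cv,tau_jitter_cv per-cell parameter jitter CVs.
#' @return data.frame (tidy): well, variant, cell_id, train_aps, frame,
#'   time_s, f; plus attribute `truth` (per-cell jittered parameters).
#' @export
generate_screen_plate <- function(variants, cfg,
                                  protocol = c(1, 2, 3, 5, 10, 20, 40, 80, 160),
                                  n_cells_per_well = 20, train_hz = 83,
                                  pre_s = 1, post_s = 6,
                                  amp_jitter_cv = 0.2, tau_jitter_cv = 0.1) {
  stopifnot(all(protocol >= 1), n_cells_per_well >= 1)
  set.seed(cfg$seed)
  rows <- list(); truth <- list()
  for (w in seq_along(variants)) {
    k <- variants[[w]]
    vname <- names(variants)[w]
    for (ci in seq_len(n_cells_per_well)) {
      aj <- exp(stats::rnorm(1, -amp_jitter_cv^2 / 2, amp_jitter_cv))
      tj <- exp(stats::rnorm(1, -tau_jitter_cv^2 / 2, tau_jitter_cv))
      a1c <- k$one_ap_amplitude * aj
      kc <- indicator_kinetics(k$name, a1c, k$half_rise_s * tj,
                               k$half_decay_s * tj,
                               amp_max = max(k$amp_max * aj, a1c))
      truth[[length(truth) + 1L]] <-
        data.frame(well = w, variant = vname, cell_id = ci,
                   one_ap_amplitude = kc$one_ap_amplitude,
                   half_decay_s = kc$half_decay_s)
      for (nap in protocol) {
        dur <- pre_s + post_s
        tt <- pre_s + (seq_len(nap) - 1) / train_hz
        st <- spike_train(tt[tt < dur], dur)
        dff <- spikes_to_dff(st, kc, cfg$fs)
        f <- cfg$f0 * (1 + dff$samples)
        if (cfg$noise_sd > 0)
          f <- f + stats::rnorm(length(f), sd = cfg$noise_sd * cfg$f0)
        nf <- length(f)
        rows[[length(rows) + 1L]] <-
          data.frame(well = w, variant = vname, cell_id = ci,
                     train_aps = nap, frame = seq_len(nf),
                     time_s = (seq_len(nf) - 1) / cfg$fs, f = f)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "pre_s") <- pre_s
  attr(out, "fs") <- cfg$fs
  out
}
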