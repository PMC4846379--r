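# Brute-force oracles used to cross-check vectorized implementations.

oracle_neuropil_correct <- function(f_meas, f_np, r) {
  out <- numeric(length(f_meas))
  for (i in seq_along(f_meas)) out[i] <- f_meas[i] - r * f_np[i]
  out
}

oracle_dot <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s
}

oracle_unit_template <- function(snips) {
  m <- numeric(ncol(snips))
  for (j in seq_len(ncol(snips))) m[j] <- mean(snips[, j])
  c0 <- m - mean(m)
  c0 / sqrt(sum(c0^2))
}

# Exhaustive event census: cluster spikes by >iso gaps, keep clusters whose
# span fits the schedule bin (singles always kept, up to max_n).
oracle_event_census <- function(times, schedule, iso = 1, max_n = 8) {
  times <- sort(times)
  clusters <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] > iso) { clusters <- c(clusters, list(cur)); cur <- t }
    else cur <- c(cur, t)
  }
  clusters <- c(clusters, list(cur))
  labs <- integer(0)
  for (cl in clusters) {
    n <- length(cl)
    if (n == 1) labs <- c(labs, 1L)
    else if (n <= max_n && (max(cl) - min(cl)) <= schedule(n) + 1e-9)
      labs <- c(labs, n)
  }
  sort(labs)
}

# Rank-sum U statistic computed by pair counting (ties get 1/2).
oracle_u_stat <- function(signal, noise) {
  u <- 0
  for (s in signal) for (x in noise)
    u <- u + (s > x) + 0.5 * (s == x)
  u
}

# A clean single-transient dF/F trace for kinetics tests.
make_transient <- function(k, fs, t_spike = 1, dur = 8) {
  spikes_to_dff(spike_train(t_spike, dur), k, fs)
}
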