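# Helper: a quiet recording at constant baseline for event extraction tests.
flat_recording <- function(dur, fs = 30, f0 = 100) {
  ca_trace(rep(f0, ceiling(dur * fs)), fs)
}

test_that("bin schedules follow the per-indicator rules", {
  sg <- ap_bin_schedule("jRGECO1a")
  expect_equal(sg(2), 0.100)
  expect_equal(sg(5), 0.175)
  expect_equal(sg(8), 0.250)
  expect_equal(sg(12), 0.250)  # capped
  sc <- ap_bin_schedule("jRCaMP1a")
  expect_equal(sc(2), 0.150)
  expect_equal(sc(6), 0.350)
  expect_equal(sc(8), 0.350)
})

test_that("event extraction: isolation, bin rule, brute-force census", {
  tr <- flat_recording(60)
  ev <- extract_events(spike_train(c(1, 10), 60), tr, post_s = 1)
  expect_equal(sort(ev$labels[ev$labels > 0]), c(1L, 1L))

  # two spikes 50 ms apart: a single 2-AP event under the jRGECO1a schedule
  ev2 <- extract_events(spike_train(c(1.00, 1.05), 60), tr)
  expect_equal(ev2$labels[ev2$labels > 0], 2L)

  # 12-spike hand-constructed train vs exhaustive enumeration
  times <- c(1, 3, 3.05,                  # 1AP + 2AP
             6, 6.06, 6.12,               # 3AP (span 120 ms <= 125 ms)
             9, 9.2, 9.5,                 # 3 spikes spanning 500 ms -> dropped
             20, 25, 25.9)                # 1AP + 2 spikes 900ms apart dropped
  ev3 <- extract_events(spike_train(times, 60), flat_recording(60))
  census <- sort(ev3$labels[ev3$labels > 0])
  expect_equal(census, oracle_event_census(times, ap_bin_schedule("jRGECO1a")))
  expect_equal(ev3$dropped, 2L)
})

test_that("event snippets use the 10-frame F0 convention on real transients", {
  k <- kinetics_preset("jRGECO1a")
  cfg <- imaging_config(fs = 30, noise_sd = 0, r_true = 0, neuropil_amp = 0,
                        seed = 1)
  dff <- spikes_to_dff(spike_train(c(5, 15), 30), k, cfg$fs)
  fov <- render_fov(dff, cfg)
  ev <- extract_events(spike_train(c(5, 15), 30), fov$f_meas)
  sig <- ev$snippets[ev$labels == 1, , drop = FALSE]
  expect_equal(nrow(sig), 2)
  expect_equal(max(sig[1, ]), k$one_ap_amplitude, tolerance = 5e-3)
})

test_that("unit templates: arithmetic, idempotence on duplicates, oracle", {
  tm <- build_unit_template(matrix(c(0, 1, 2), 1))
  expect_equal(tm$unit, c(-1, 0, 1) / sqrt(2))
  tm2 <- build_unit_template(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(tm2$unit, tm$unit)
  set.seed(7)
  snips <- matrix(rnorm(60), 6, 10)
  expect_equal(build_unit_template(snips)$unit, oracle_unit_template(snips))
  expect_error(build_unit_template(matrix(1, 2, 4)), "constant")
})

test_that("projection is the raw inner product", {
  set.seed(8)
  snips <- matrix(rnorm(50), 5, 10)
  tm <- build_unit_template(snips)
  centered <- tm$template - mean(tm$template)
  expect_equal(project_snippets(centered, tm$unit), sqrt(sum(centered^2)))
  ortho <- c(rep(1, 10))  # constant is orthogonal to the zero-mean unit
  expect_lt(abs(project_snippets(ortho, tm$unit)), 1e-12)
  scores <- project_snippets(snips, tm$unit)
  oracle <- apply(snips, 1, oracle_dot, b = tm$unit)
  expect_equal(scores, oracle)
})

test_that("d-prime: analytic value, null behavior, scale invariance", {
  set.seed(9)
  s <- rnorm(1e4, 1); n0 <- rnorm(1e4)
  d <- dprime(s, n0)
  expect_lt(abs(d - 1), 0.05)
  expect_equal(dprime(10 * s, 10 * n0), d, tolerance = 1e-12)
  same <- dprime(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(same), 3 * sqrt(2 / 1e4) * 1.5)
  expect_warning(dprime(rep(1, 5), rep(0, 5)), "zero pooled variance")
})

test_that("ROC: hand-enumerated points, separation, AUC equals U/(ns*nn)", {
  roc <- roc_curve(c(3, 4), c(1, 2))
  expect_equal(roc$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 1, 1, 1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect separation
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(attr(roc, "auc"), 1)

  set.seed(10)
  s <- rnorm(150, 0.8); n0 <- rnorm(130)
  roc2 <- roc_curve(s, n0)
  expect_equal(attr(roc2, "auc"),
               oracle_u_stat(s, n0) / (length(s) * length(n0)),
               tolerance = 1e-12)
})

test_that("accuracy at fixed FPR: separation, chance level, warnings", {
  acc <- accuracy_at_fpr(c(10, 11, 12), 1:100 / 100, 0.05)
  expect_equal(acc$tpr, 1)
  set.seed(11)
  x <- rnorm(2e4)
  chance <- accuracy_at_fpr(rnorm(2e4), x, 0.05)
  expect_lt(abs(chance$tpr - 0.05), 0.01)
  expect_warning(accuracy_at_fpr(rnorm(10), rnorm(5), 0.05),
                 "conservative")
})

test_that("end-to-end detection improves with AP count on generated events", {
  k <- kinetics_preset("jRGECO1a")
  cfg <- imaging_config(fs = 30, noise_sd = 0.05, r_true = 0,
                        neuropil_amp = 0, seed = 12)
  ev <- generate_ap_event_dataset(c("1" = 40, "2" = 40, "4" = 40),
                                  n_noise = 60, k, cfg)
  res <- detect_analysis(ev, fpr_target = 0.05)
  expect_equal(res$per_class$n_ap, c(1, 2, 4))
  expect_true(all(diff(res$per_class$dprime) > 0))
  expect_true(all(diff(res$per_class$accuracy) >= 0))
  # ROC invariants
  for (roc in res$roc) {
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  }
})
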