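test_that("kinetics presets carry published half-decay values and reject unknowns", {
  expect_equal(kinetics_preset("jRGECO1a")$half_decay_s, 0.39)
  expect_equal(kinetics_preset("jRCaMP1a")$half_decay_s, 0.64)
  expect_equal(kinetics_preset("jRGECO1a", "nmj")$one_ap_amplitude, 0.116)
  expect_equal(kinetics_preset("jRCaMP1a", "nmj")$one_ap_amplitude, 0.086)
  expect_equal(kinetics_preset("GCaMP6s", "nmj")$one_ap_amplitude, 0.045)
  expect_equal(kinetics_preset("jRGECO1a", "nmj")$half_decay_s, 0.42)
  expect_error(kinetics_preset("notAnIndicator"), "unknown indicator preset")
})

test_that("amplitude curves start at the 1-AP amplitude and are nondecreasing", {
  for (ctx in c("invivo", "nmj", "culture")) {
    for (nm in kinetics_presets(ctx)) {
      k <- kinetics_preset(nm, ctx)
      av <- k$amplitude_curve(1:160)
      expect_equal(av[1], k$one_ap_amplitude)
      expect_true(all(diff(av) >= -1e-12))
      expect_true(all(av >= 0))
    }
  }
})

test_that("kernel tau solver reproduces the requested half-times", {
  cases <- list(c(0.03, 0.39), c(0.08, 0.64), c(0.02, 0.42), c(0.1, 1.0))
  for (cs in cases) {
    taus <- solve_kernel_taus(cs[1], cs[2])
    ht <- gecibench:::kernel_half_times(taus[["tau_r"]], taus[["tau_d"]])
    expect_equal(unname(ht[1]), cs[1], tolerance = 1e-4)
    expect_equal(unname(ht[2]), cs[2], tolerance = 1e-4)
  }
  # tail anchoring pins the decay time constant directly
  taus <- solve_kernel_taus(0.02, 0.42, decay_anchor = "tail")
  expect_equal(unname(taus[["tau_d"]]), 0.42 / log(2))
  ht <- gecibench:::kernel_half_times(taus[["tau_r"]], taus[["tau_d"]])
  expect_equal(unname(ht[["half_rise"]]), 0.02, tolerance = 1e-6)
})

test_that("spikes_to_dff: empty train, single-spike peak, superposition", {
  k <- kinetics_preset("jRGECO1a")
  fs <- 200
  z <- spikes_to_dff(spike_train(numeric(0), 5), k, fs)
  expect_equal(z$samples, rep(0, 1000))

  one <- spikes_to_dff(spike_train(1, 5), k, fs)
  expect_equal(max(one$samples), k$one_ap_amplitude, tolerance = 2e-3)

  # spikes 5 s apart superpose additively (elementwise)
  a <- spikes_to_dff(spike_train(1, 20), k, fs)
  b <- spikes_to_dff(spike_train(6, 20), k, fs)
  ab <- spikes_to_dff(spike_train(c(1, 6), 20), k, fs)
  expect_equal(ab$samples, a$samples + b$samples, tolerance = 1e-12)

  # two spikes within the burst window form one 2-AP burst
  burst <- spikes_to_dff(spike_train(c(1, 1.05), 5), k, fs)
  expect_equal(max(burst$samples), k$amplitude_curve(2), tolerance = 2e-3)
})

test_that("render_fov is exact when noiseless and reproducible from seed", {
  k <- kinetics_preset("jRGECO1a")
  dff <- spikes_to_dff(spike_train(c(1, 3), 6), k, 30)
  cfg0 <- imaging_config(fs = 30, f0 = 50, noise_sd = 0, r_true = 0,
                         neuropil_amp = 0, seed = 7)
  fov0 <- render_fov(dff, cfg0)
  expect_equal(fov0$f_meas$samples, 50 * (1 + dff$samples))

  cfg <- imaging_config(fs = 30, f0 = 50, noise_sd = 0, r_true = 0.7,
                        neuropil_amp = 0.05, seed = 7)
  fov <- render_fov(dff, cfg)
  corr <- neuropil_correct(fov$f_meas, fov$f_np, r = 0.7)
  expect_equal(corr$samples, 50 * (1 + dff$samples), tolerance = 1e-12)

  fov2 <- render_fov(dff, cfg)
  expect_identical(fov$f_meas$samples, fov2$f_meas$samples)
  expect_identical(fov$f_np$samples, fov2$f_np$samples)
})

test_that("render_fov noise level matches the configured sd", {
  k <- kinetics_preset("jRGECO1a")
  dff <- spikes_to_dff(spike_train(numeric(0), 400), k, 25)  # 1e4 frames
  cfg <- imaging_config(fs = 25, f0 = 100, noise_sd = 0.02, r_true = 0.4,
                        neuropil_amp = 0.03, seed = 3)
  fov <- render_fov(dff, cfg)
  resid <- (fov$f_meas$samples - cfg$r_true * fov$f_np$samples -
              cfg$f0 * (1 + dff$samples)) / cfg$f0
  mc_err <- 0.02 / sqrt(2 * (length(resid) - 1))
  expect_lt(abs(sd(resid) - 0.02), 3 * mc_err)
})

test_that("noiseless chain recovers ground-truth dF/F to 1e-9", {
  k <- kinetics_preset("jRGECO1a")
  # spike placed after a quiet baseline so the F0 window is clean
  dff <- spikes_to_dff(spike_train(2, 8), k, 30)
  cfg <- imaging_config(fs = 30, f0 = 80, noise_sd = 0, r_true = 0.7,
                        neuropil_amp = 0, seed = 1)
  fov <- render_fov(dff, cfg)
  corr <- neuropil_correct(fov$f_meas, fov$f_np, 0.7)
  f0 <- compute_f0(corr, c(0, 1))
  rec <- compute_dff(corr, f0)
  expect_lt(max(abs(rec$samples - dff$samples)), 1e-9)
})

test_that("depth-profile generator: exact recovery when noiseless, errors on bad lambda", {
  prof <- generate_depth_profiles(3, 100, seq(100, 400, 20), noise_cv = 0,
                                  seed = 1)
  fits <- fit_depth_profiles(prof)
  expect_equal(fits$lambda_um, rep(100, 3), tolerance = 1e-9)
  expect_error(generate_depth_profiles(3, Inf, seq(100, 400, 20)),
               "finite")
  expect_error(generate_depth_profiles(3, -5, seq(100, 400, 20)), "finite")
})

test_that("AP-event dataset honors class counts, labels, and seed determinism", {
  k <- kinetics_preset("jRGECO1a")
  cfg <- imaging_config(fs = 30, noise_sd = 0.01, r_true = 0,
                        neuropil_amp = 0, seed = 9)
  ev <- generate_ap_event_dataset(c("1" = 5, "2" = 3), n_noise = 4, k, cfg)
  expect_equal(sum(ev$labels == 1), 5)
  expect_equal(sum(ev$labels == 2), 3)
  expect_equal(sum(ev$labels == 0), 4)
  expect_equal(nrow(ev$snippets), 12)

  ev2 <- generate_ap_event_dataset(c("1" = 5, "2" = 3), n_noise = 4, k, cfg)
  expect_identical(ev$snippets, ev2$snippets)
  expect_identical(ev$labels, ev2$labels)

  # noiseless: every event snippet peak equals the amplitude curve
  cfg0 <- imaging_config(fs = 30, noise_sd = 0, r_true = 0,
                         neuropil_amp = 0, seed = 9)
  ev0 <- generate_ap_event_dataset(c("1" = 3, "3" = 2), n_noise = 2, k, cfg0)
  for (i in which(ev0$labels > 0)) {
    expect_equal(max(ev0$snippets[i, ]),
                 k$amplitude_curve(ev0$labels[i]), tolerance = 5e-3)
  }
})

test_that("screen plate has the expected structure and noiseless saturation", {
  k <- kinetics_preset("jRGECO1a", "culture")
  cfg <- imaging_config(fs = 35, noise_sd = 0, seed = 2)
  plate <- generate_screen_plate(list(jRGECO1a = k), cfg,
                                 protocol = c(1, 10, 160),
                                 n_cells_per_well = 3,
                                 amp_jitter_cv = 0, tau_jitter_cv = 0)
  frames_per_trace <- ceiling(7 * 35)
  expect_equal(nrow(plate), 3 * 3 * frames_per_trace)
  m <- well_metrics(plate)
  expect_equal(nrow(m), 3 * 3)  # cells x trains
  p160 <- m$peak_dff[m$train_aps == 160]
  expect_equal(p160, rep(k$amplitude_curve(160), 3), tolerance = 5e-3)
})

test_that("tuned population: structure, type-I behavior and detection power", {
  k <- kinetics_preset("jRGECO1a")
  cfg <- imaging_config(fs = 15, noise_sd = 0.01, seed = 21)
  pop <- generate_tuned_population(12, frac_responsive = 1, k, cfg)
  expect_length(pop$recordings, 12)
  # 40 trials x 8 s per trial x 15 frames/s
  expect_equal(length(pop$recordings[[1]]$f_meas$samples), 40 * 8 * 15)
  res <- analyze_population_tuning(pop)
  expect_gte(mean(res$responsive), 0.95)

  cfg2 <- imaging_config(fs = 15, noise_sd = 0.01, seed = 22)
  pop0 <- generate_tuned_population(30, frac_responsive = 0, k, cfg2)
  res0 <- analyze_population_tuning(pop0)
  # under the null the flagged fraction stays near the ANOVA level
  expect_lte(sum(res0$responsive), 1 + qbinom(0.999, 30, 0.01))
})
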