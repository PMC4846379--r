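dirs <- seq(0, 315, by = 45)

# trial_table built from a known stim/blank matrix
tt_from <- function(stim_means, blank = matrix(0, 8, 5)) {
  rownames(stim_means) <- as.character(dirs)
  rownames(blank) <- as.character(dirs)
  trial_table(stim_means, blank)
}

test_that("build_trial_table recovers per-trial stimulus means", {
  sched <- stimulus_schedule()
  fs <- 10
  n <- 40 * 8 * fs
  # dF/F = 0.2 during every stimulus period, 0 in blanks
  dff <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(sched)))
    dff[tt >= sched$stim_start[i] & tt < sched$stim_end[i]] <- 0.2
  f <- ca_trace(100 * (1 + dff), fs)
  tab <- build_trial_table(f, sched)
  expect_s3_class(tab, "trial_table")
  expect_equal(dim(tab$stim), c(8, 5))
  expect_equal(as.vector(tab$stim), rep(0.2, 40), tolerance = 1e-12)
  expect_equal(as.vector(tab$blank), rep(0, 40), tolerance = 1e-12)

  # truncated recording -> misalignment error
  f_short <- ca_trace(f$samples[1:(n / 2)], fs)
  expect_error(build_trial_table(f_short, sched), "past the end")
})

test_that("responsiveness requires both the response gate and the ANOVA", {
  tab0 <- tt_from(matrix(0, 8, 5))
  expect_false(classify_responsive(tab0)$responsive)

  stim <- matrix(0, 8, 5); stim[3, ] <- 1
  expect_true(classify_responsive(tt_from(stim))$responsive)

  # strong modulation but below the dF/F gate -> not responsive
  expect_false(classify_responsive(tt_from(stim * 0.04))$responsive)

  # type-I at the null stays near alpha (gate only lowers it)
  set.seed(10)
  nrep <- 400
  hits <- 0
  for (i in seq_len(nrep)) {
    tab <- tt_from(matrix(rnorm(40, 0, 0.2), 8, 5),
                   matrix(rnorm(40, 0, 0.2), 8, 5))
    hits <- hits + classify_responsive(tab, dff_min = -Inf)$responsive
  }
  expect_lte(hits, qbinom(0.999, nrep, 0.01))
})

test_that("preferred stimulus takes the argmax with low-label tie-breaking", {
  stim <- matrix(0, 8, 5); stim[dirs == 90, ] <- 1
  expect_equal(preferred_stimulus(tt_from(stim)), 90)
  stim2 <- matrix(0, 8, 5)
  stim2[dirs == 45, ] <- 1; stim2[dirs == 225, ] <- 1
  expect_equal(preferred_stimulus(tt_from(stim2)), 45)
})

test_that("double-Gaussian fit recovers noiseless model parameters", {
  truth <- list(theta_pref = 135, sigma = 30, a1 = 0.6, a2 = 0.2, b = 0.1,
                delta_deg = 180)
  y <- gecibench:::dg_model(dirs, c(theta_pref = 135, sigma = 30, a1 = 0.6,
                                    a2 = 0.2, b = 0.1), 180)
  tab <- tt_from(matrix(rep(y, 5), 8, 5))
  fit <- fit_tuning(tab, delta_deg = 180)
  expect_lt(abs(fit$theta_pref - truth$theta_pref), 135 * 0.01)
  expect_lt(abs(fit$sigma - truth$sigma) / truth$sigma, 0.01)
  expect_lt(abs(fit$a1 - truth$a1) / truth$a1, 0.01)
  expect_lt(abs(fit$a2 - truth$a2) / truth$a2, 0.02)
  expect_lt(abs(fit$b - truth$b) / truth$b, 0.05)
  expect_equal(fit$osi, compute_osi(fit))

  flat <- fit_tuning(tt_from(matrix(0.3, 8, 5)))
  expect_true(flat$degenerate)
})

test_that("OSI: arithmetic, boundary cases, and scale invariance", {
  f <- list(theta_pref = 0, sigma = 10, a1 = 0.6, a2 = 0.2, b = 0,
            delta_deg = 90)
  expect_equal(compute_osi(f), (0.6 - 0.2) / (0.6 + 0.2), tolerance = 1e-6)
  f1 <- list(theta_pref = 0, sigma = 10, a1 = 0.5, a2 = 0, b = 0,
             delta_deg = 90)
  expect_equal(compute_osi(f1), 1, tolerance = 1e-6)
  f2 <- list(theta_pref = 0, sigma = 10, a1 = 0.4, a2 = 0.4, b = 0,
             delta_deg = 90)
  expect_equal(compute_osi(f2), 0, tolerance = 1e-6)
  # invariance under multiplicative scaling of the tuning curve
  fs_ <- list(theta_pref = 70, sigma = 25, a1 = 0.3, a2 = 0.1, b = 0.05,
              delta_deg = 180)
  fscaled <- utils::modifyList(fs_, list(a1 = 3, a2 = 1, b = 0.5))
  expect_equal(compute_osi(fs_), compute_osi(fscaled), tolerance = 1e-12)
})

test_that("tuning recovery on generated cells matches ground truth", {
  k <- kinetics_preset("jRGECO1a")
  cfg <- imaging_config(fs = 15, noise_sd = 0.005, seed = 31)
  pop <- generate_tuned_population(15, frac_responsive = 1, k, cfg)
  res <- analyze_population_tuning(pop)
  truth <- pop$truth
  ok <- res$responsive
  expect_gte(mean(ok), 0.95)
  err <- gecibench:::circ_dist_deg(res$theta_pref[ok], truth$theta_pref[ok])
  # direction-tuned cells: allow the 180-degree lobe ambiguity
  err <- pmin(err, abs(err - 180))
  expect_lt(median(err), truth$sigma[1] / 2)
})
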