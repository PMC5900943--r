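test_that("zero amplitudes without noise give a flat recording at baseline", {
  amp0 <- default_amplitude_table(
    visual_means = c("LR" = 0, "HR-noASD" = 0, "HR-ASD" = 0),
    vocal_diffs = c("LR" = 0, "HR-noASD" = 0, "HR-ASD" = 0),
    auditory_base = 0)
  cfg <- quiet_config(amplitudes = amp0)
  sched <- build_stimulus_schedule(1, seed = 3)
  sim <- simulate_infant(cfg, "LR", sched, seed = 4)
  expect_true(all(abs(sim$recording$intensity - 1) < 1e-12))
})

test_that("the forward model round-trips through preprocessing at the peak", {
  # single visual-social trial, peak-referenced amplitude 0.45 uM
  cfg <- quiet_config(amplitude_reference = "peak")
  sched <- build_stimulus_schedule(1, seed = 42)[1:3, ]  # REF, V-S, REF
  sim <- simulate_infant(cfg, "LR", sched, seed = 7)
  fs <- cfg$sampling_rate_hz
  n_t <- dim(sim$recording$intensity)[3]
  clean_full <- 0.45 * nirsocial:::condition_response(sched, "V-S", fs, n_t,
                                                      cfg$hrf, "peak")
  onset_idx <- round(sched$onset_s[2] * fs) + 1L

  # chain without the block detrend: recovery is exact up to a constant,
  # removed by referencing the pre-stimulus baseline
  blocks <- preprocess_recording(sim$recording, sched, detrend = FALSE)
  b <- blocks$blocks[[1]]
  nb <- ncol(b$hbo)
  clean <- clean_full[(onset_idx - 40):(onset_idx - 41 + nb)]
  ch <- 1L  # left IFG carries the visual-social response
  rec <- b$hbo[ch, ] - mean(b$hbo[ch, b$rel_time >= -4 & b$rel_time < 0])
  pk <- which.max(clean)
  expect_lt(abs(rec[pk] - clean[pk]), 1e-6)
  expect_lt(abs(clean[pk] - 0.45), 1e-9)
  expect_lt(max(abs(rec - clean)), 1e-5)

  # with detrending, the chain reproduces the identically detrended clean
  # concentration (linearity of every stage); the detrend anchors touch the
  # recording edge, so the filter's end transient sets the tolerance here
  blocks_dt <- preprocess_recording(sim$recording, sched, detrend = TRUE)
  bd <- blocks_dt$blocks[[1]]
  clean_dt <- detrend_block(clean, bd$rel_time)
  expect_lt(max(abs(bd$hbo[ch, ] - clean_dt)), 1e-5)

  # deoxy-haemoglobin is the configured negative fraction
  expect_equal(bd$hhb[ch, ], -clean_dt / 3, tolerance = 1e-5)
})

test_that("whole-chain response is linear in the injected amplitude", {
  sched <- build_stimulus_schedule(1, seed = 10)
  out <- lapply(c(1, 3), function(k) {
    amp <- default_amplitude_table(
      visual_means = k * c("LR" = 0.3, "HR-noASD" = 0.2, "HR-ASD" = 0.1),
      vocal_diffs = k * c("LR" = 0.2, "HR-noASD" = 0, "HR-ASD" = -0.4),
      auditory_base = k * 0.3)
    cfg <- quiet_config(amplitudes = amp)
    sim <- simulate_infant(cfg, "LR", sched, seed = 5)
    blocks <- preprocess_recording(sim$recording, sched)
    blocks$blocks[[1]]$hbo
  })
  expect_equal(out[[2]], 3 * out[[1]], tolerance = 1e-8)
})

test_that("degenerate looking makes every trial valid under the 60% rule", {
  cfg <- quiet_config()
  sched <- build_stimulus_schedule(1, seed = 6)
  sim <- simulate_infant(cfg, "HR-ASD", sched, seed = 8)
  flags <- looking_validity(sim$looking)
  expect_true(all(flags$looking_valid))
})

test_that("simulation rejects invalid arguments", {
  cfg <- quiet_config()
  sched <- build_stimulus_schedule(1, seed = 1)
  expect_error(simulate_infant(cfg, "not-a-group", sched), "unknown group")
  expect_error(simulate_infant(cfg, "LR", sched[0, ]), "empty")
  expect_error(sim_config(sampling_rate_hz = 3), "cutoff")
  expect_error(sim_config(group_sizes = c("LR" = -1, "HR-noASD" = 1,
                                          "HR-ASD" = 1)), ">= 0")
})

test_that("identical configuration and seed give bit-identical cohorts", {
  cfg <- sim_config(probe = small_probe_map(), sampling_rate_hz = 5,
                    group_sizes = c("LR" = 2, "HR-noASD" = 2, "HR-ASD" = 1),
                    seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$infants[[3]]$recording$intensity,
                   c2$infants[[3]]$recording$intensity)
  expect_identical(c1$infants[[5]]$looking, c2$infants[[5]]$looking)
})

test_that("default cohort matches the analysed sample structure", {
  cfg <- quiet_config(sampling_rate_hz = 5, seed = 12)
  coh <- simulate_cohort(cfg)
  expect_length(coh$infants, 36L)
  expect_equal(as.vector(table(coh$phenotypes$group)[c("LR", "HR-noASD",
                                                       "HR-ASD")]),
               c(16L, 15L, 5L))
  expect_equal(recurrence_rate(coh$phenotypes), 0.25)
})

test_that("ground truth logs consistent injected quantities", {
  cfg <- sim_config(probe = small_probe_map(), sampling_rate_hz = 5,
                    artifacts = artifact_spec(spike_prob = 0.5,
                                              shift_prob = 0.5), seed = 31)
  sched <- build_stimulus_schedule(1, seed = 31)
  sim <- simulate_infant(cfg, "LR", sched, seed = 32)
  tr <- sim$truth
  expect_true(all(is.finite(tr$amplitudes$amplitude)))
  exp_ids <- experimental_trials(sched)$trial_id
  expect_true(all(tr$artifacts$trial_id %in% exp_ids))
  n_t <- dim(sim$recording$intensity)[3]
  expect_true(all(tr$artifacts$sample >= 1 & tr$artifacts$sample <= n_t))
  expect_length(tr$looking, length(exp_ids))
})

test_that("SRS decouples from the injected social amplitude at zero coupling", {
  cfg <- quiet_config(sampling_rate_hz = 5,
                      group_sizes = c("LR" = 200, "HR-noASD" = 0,
                                      "HR-ASD" = 0),
                      srs = srs_spec(coupling = 0),
                      amplitude_sd = c(social = 0.3, vocal = 0.6),
                      seed = 90)
  coh <- simulate_cohort(cfg)
  social <- vapply(coh$infants, function(x) x$truth$social_amplitude,
                   numeric(1))
  expect_lt(abs(stats::cor(social, coh$phenotypes$srs_total)), 0.2)
})

test_that("negative coupling induces the configured SRS correlation", {
  cfg <- quiet_config(sampling_rate_hz = 5,
                      group_sizes = c("LR" = 200, "HR-noASD" = 0,
                                      "HR-ASD" = 0),
                      srs = srs_spec(coupling = -0.5),
                      amplitude_sd = c(social = 0.3, vocal = 0.6),
                      seed = 91)
  coh <- simulate_cohort(cfg)
  social <- vapply(coh$infants, function(x) x$truth$social_amplitude,
                   numeric(1))
  r <- stats::cor(social, coh$phenotypes$srs_total)
  expect_lt(r, -0.35)
  expect_gt(r, -0.65)
})

test_that("expected attrition increases with the inattentive-trial probability", {
  # per-trial invalidity probability, estimated from the looking model alone
  p_invalid <- vapply(c(0.05, 0.2, 0.5), function(pi) {
    set.seed(123)
    mean(nirsocial:::sample_looking(looking_spec(inattentive_prob = pi),
                                    20000) <= 0.6)
  }, numeric(1))
  expect_true(all(diff(p_invalid) > 0))
  # implied probability that an infant fails the >=3-of-4 rule in any of the
  # three conditions is monotone in the per-trial probability
  p_cond_fail <- stats::pbinom(2, 4, 1 - p_invalid)
  fail_rate <- 1 - (1 - p_cond_fail)^3
  expect_true(all(diff(fail_rate) > 0))
})
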