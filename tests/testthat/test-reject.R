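test_that("looking validity applies the strict 60% rule", {
  looking <- data.frame(trial_id = 1:4, looking = c(0.59, 0.61, 1.0, NA))
  flags <- looking_validity(looking)
  expect_identical(flags$looking_valid, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(flags$reason,
                   c("insufficient_looking", NA, NA, "uncoded"))
  # exactly at threshold is invalid (strict inequality)
  expect_false(looking_validity(data.frame(trial_id = 1,
                                           looking = 0.60))$looking_valid)
  expect_error(looking_validity(data.frame(trial_id = 1, looking = 1.2)),
               "\\[0, 1\\]")
})

test_that("intensity scan retains clean and constant channels, rejects spiky ones", {
  set.seed(21)
  n_t <- 1000
  probe <- small_probe_map()[1:3, ]
  x <- array(0, c(3, 2, n_t))
  for (wl in 1:2) {
    x[1, wl, ] <- 1 + stats::rnorm(n_t, 0, 0.005)   # clean
    x[2, wl, ] <- 2                                 # constant: CV = 0
    spiky <- 1 + stats::rnorm(n_t, 0, 0.01)
    idx <- sample.int(n_t, 50)                      # spikes on 5% of samples
    spiky[idx] <- spiky[idx] + 0.12                 # >> 10 robust SD
    x[3, wl, ] <- spiky
  }
  rec <- nirs_recording(x, probe, 10)
  flags <- intensity_artifact_scan(rec, cv_max = 0.10, spike_z = 10,
                                   frac_max = 0.01)
  expect_identical(flags$intensity_artifact, c(FALSE, FALSE, TRUE))
  expect_equal(flags$cv[2], 0)
  # brute-force count of the spike fraction matches the rule
  expect_gt(flags$spike_frac[3], 0.01)
})

test_that("concentration scan flags jumps with a strict threshold", {
  fs <- 10
  n <- 241
  clean <- matrix(0.1 * sin(seq(0, 4 * pi, length.out = n)), 1, n)
  step2 <- clean; step2[1, 120:n] <- step2[1, 120:n] + 2.0   # 2 x threshold
  stepx <- matrix(0, 1, n); stepx[1, 120:n] <- 1.0           # exactly at it
  blocks <- make_blocks(list(clean, step2, stepx),
                        c("V-S", "A-V", "A-NV"),
                        probe = small_probe_map()[1, ])
  flags <- concentration_artifact_scan(blocks, jump_umol = 1.0,
                                       window_s = 0.5)
  expect_identical(flags$concentration_artifact, c(FALSE, TRUE, FALSE))
})

test_that("inclusion rules enforce three valid trials per condition", {
  probe <- small_probe_map()
  mk_ledger <- function(valid_by_cond) {
    conds <- rep(c("V-S", "A-V", "A-NV"), each = 4)
    trials <- seq_along(conds) * 2L
    do.call(rbind, lapply(probe$channel_id, function(ch) {
      data.frame(channel_id = ch, trial_id = trials, condition = conds,
                 looking_invalid = FALSE, intensity_artifact = FALSE,
                 concentration_artifact = FALSE, incomplete_block = FALSE,
                 valid = unlist(lapply(c("V-S", "A-V", "A-NV"), function(cc)
                   seq_len(4) <= valid_by_cond[[cc]])))
    }))
  }
  # (V-S: 4, A-V: 4, A-NV: 2) valid -> infant excluded (the two-trial
  # condition disqualifies every channel, hence the infant)
  res <- apply_inclusion_rules(mk_ledger(list("V-S" = 4, "A-V" = 4,
                                              "A-NV" = 2)), probe)
  expect_false(res$infant_included)
  expect_false(is.na(res$reason))
  # valid in only two conditions -> channels excluded
  res2 <- apply_inclusion_rules(mk_ledger(list("V-S" = 4, "A-V" = 4,
                                               "A-NV" = 0)), probe)
  expect_true(all(!res2$channels$included))
  # everything valid -> everything included
  res3 <- apply_inclusion_rules(mk_ledger(list("V-S" = 4, "A-V" = 4,
                                               "A-NV" = 4)), probe)
  expect_true(res3$infant_included)
  expect_true(res3$visual_included)
  expect_true(all(res3$channels$included))
})

test_that("an infant without valid IFG channels is excluded from the visual analysis only", {
  probe <- small_probe_map()
  conds <- rep(c("V-S", "A-V", "A-NV"), each = 4)
  trials <- seq_along(conds) * 2L
  led <- do.call(rbind, lapply(probe$channel_id, function(ch) {
    data.frame(channel_id = ch, trial_id = trials, condition = conds,
               looking_invalid = FALSE,
               intensity_artifact = probe$roi[probe$channel_id == ch] == "IFG",
               concentration_artifact = FALSE, incomplete_block = FALSE,
               valid = probe$roi[probe$channel_id == ch] != "IFG")
  }))
  res <- apply_inclusion_rules(led, probe)
  expect_true(res$infant_included)
  expect_false(res$visual_included)
})

test_that("relaxing thresholds never shrinks the valid set", {
  cfg <- sim_config(probe = small_probe_map(), sampling_rate_hz = 5,
                    artifacts = artifact_spec(spike_prob = 0.3,
                                              shift_prob = 0.2),
                    looking = looking_spec(inattentive_prob = 0.3),
                    group_sizes = c("LR" = 3, "HR-noASD" = 0, "HR-ASD" = 0),
                    seed = 61)
  coh <- simulate_cohort(cfg)
  strict <- analysis_options(jump_umol = 0.5, cv_max = 0.05, spike_z = 3,
                             spike_frac_max = 0.005, looking_threshold = 0.8)
  relaxed <- analysis_options(jump_umol = 2, cv_max = 0.2, spike_z = 8,
                              spike_frac_max = 0.05, looking_threshold = 0.6)
  for (inf in coh$infants) {
    r_strict <- infant_responses(inf$recording, inf$schedule, inf$looking,
                                 strict, peaks = FALSE)
    r_relaxed <- infant_responses(inf$recording, inf$schedule, inf$looking,
                                  relaxed, peaks = FALSE)
    key <- function(l) paste(l$channel_id, l$trial_id)
    valid_strict <- key(r_strict$ledger)[r_strict$ledger$valid]
    valid_relaxed <- key(r_relaxed$ledger)[r_relaxed$ledger$valid]
    expect_true(all(valid_strict %in% valid_relaxed))
    # ledger accounting: presented = valid + flagged
    led <- r_relaxed$ledger
    expect_equal(sum(led$valid) +
                   sum(led$looking_invalid | led$intensity_artifact |
                         led$concentration_artifact | led$incomplete_block),
                 nrow(led))
  }
})

test_that("study accounting rates are computed from counts", {
  expect_equal(inclusion_rate(60, 24), 0.6)
  expect_error(inclusion_rate(0, 0))
  ph <- data.frame(group = c(rep("LR", 16), rep("HR-noASD", 15),
                             rep("HR-ASD", 5)))
  expect_equal(recurrence_rate(ph), 0.25)
  expect_error(recurrence_rate(data.frame(group = rep("LR", 3))),
               "high-risk")
})
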