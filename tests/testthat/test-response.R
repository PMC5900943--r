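fs <- 10
n_keep <- 241  # [-4, 20] s at 10 Hz
rel <- (seq_len(n_keep) - 41) / fs

test_that("averaging identical valid trials reproduces the single trial", {
  x <- matrix(sin(rel), 1, n_keep)
  blocks <- make_blocks(rep(list(x), 12),
                        rep(c("V-S", "A-V", "A-NV"), 4),
                        probe = small_probe_map()[1, ])
  ledger <- all_valid_ledger(blocks)
  avg <- average_trials(blocks, ledger)
  expect_equal(avg$hbo[1, "V-S", ], sin(rel), tolerance = 1e-12)
  expect_equal(unname(avg$n_trials[1, ]), c(4L, 4L, 4L))
})

test_that("fewer than three valid trials leaves the cell absent", {
  x <- matrix(1.0, 1, n_keep)
  blocks <- make_blocks(rep(list(x), 6),
                        c("V-S", "V-S", "A-V", "A-V", "A-NV", "A-NV"),
                        probe = small_probe_map()[1, ])
  ledger <- all_valid_ledger(blocks)
  avg <- average_trials(blocks, ledger)
  expect_true(all(is.na(avg$hbo[1, "V-S", ])))
  expect_equal(unname(avg$n_trials[1, "V-S"]), 0L)
  expect_equal(nrow(window_peaks(avg)), 0L)
})

test_that("averaged trials converge to the underlying response as n grows", {
  set.seed(14)
  shape <- 0.4 * hrf_gamma(rel, 10)
  rmse <- vapply(c(4, 64), function(n) {
    trials <- lapply(seq_len(n), function(i) {
      matrix(shape + stats::rnorm(n_keep, 0, 0.3), 1, n_keep)
    })
    blocks <- make_blocks(trials, rep(c("V-S", "A-V", "A-NV"),
                                      length.out = n),
                          probe = small_probe_map()[1, ])
    avg <- average_trials(blocks, all_valid_ledger(blocks), min_trials = 1)
    sqrt(mean((avg$hbo[1, "V-S", ] - shape)^2))
  }, numeric(1))
  # 16x the trials -> about 4x smaller error
  expect_lt(rmse[2], rmse[1] / 2)
})

test_that("windowed peaks implement the signed extremum minus baseline", {
  expect_equal(window_peak(rep(2.2, n_keep), rel), 0, tolerance = 1e-12)
  # gamma response peaking at 10 s with amplitude 0.45 over a flat baseline
  x <- 0.45 * hrf_gamma(rel, 10)
  expect_equal(window_peak(x, rel, c(8, 12), "HbO2"), 0.45,
               tolerance = 1e-6)
  # deoxy dip of -0.15 at 11 s: the extremum is the minimum
  xh <- -0.15 * hrf_gamma(rel, 11)
  expect_equal(window_peak(xh, rel, c(8, 12), "HHb"), -0.15,
               tolerance = 1e-6)
  expect_error(window_peak(x[1:50], rel[1:50], c(8, 12)), "cover")
})

test_that("epoch summaries integrate a ramp exactly", {
  vals <- epoch_summarize(rel, rel)  # identity ramp in seconds
  expect_equal(unname(vals), c(1.95, 5.95, 9.95, 13.95, 17.95),
               tolerance = 1e-9)
})

test_that("window and epoch statistics are offset-invariant and scale-equivariant", {
  set.seed(15)
  x <- stats::rnorm(n_keep)
  for (c0 in c(-3, 0.7)) {
    expect_equal(epoch_summarize(x + c0, rel), epoch_summarize(x, rel),
                 tolerance = 1e-9)
    expect_equal(window_peak(x + c0, rel), window_peak(x, rel),
                 tolerance = 1e-9)
  }
  expect_equal(epoch_summarize(2.5 * x, rel), 2.5 * epoch_summarize(x, rel),
               tolerance = 1e-9)
  expect_equal(window_peak(2.5 * x, rel, c(8, 12)),
               2.5 * window_peak(x, rel, c(8, 12)), tolerance = 1e-9)
})

test_that("ROI averages pool an infant's retained channels", {
  probe <- small_probe_map()
  epochs <- data.frame(channel_id = c(1L, 4L), condition = "V-S",
                       chromophore = "HbO2", epoch = "8-12",
                       value = c(0.2, 0.4))
  incl <- data.frame(channel_id = probe$channel_id, included = TRUE)
  # channels 1 (left IFG) and 4 (right IFG) average within hemisphere cells
  roi <- roi_average(epochs, probe, incl)
  expect_equal(roi$value[roi$hemisphere == "left"], 0.2)
  expect_equal(roi$value[roi$hemisphere == "right"], 0.4)
  # same-ROI, same-hemisphere channels are averaged; rejected ones drop out
  probe2 <- data.frame(channel_id = 1:2, hemisphere = "left",
                       separation_cm = 2, roi = "IFG")
  probe2 <- rbind(probe2, data.frame(channel_id = 3, hemisphere = "right",
                                     separation_cm = 2, roi = "IFG"))
  ep2 <- data.frame(channel_id = c(1L, 2L, 3L), condition = "V-S",
                    chromophore = "HbO2", epoch = "8-12",
                    value = c(0.2, 0.4, 0.9))
  incl2 <- data.frame(channel_id = 1:3, included = TRUE)
  roi2 <- roi_average(ep2, probe2, incl2)
  expect_equal(roi2$value[roi2$hemisphere == "left"], 0.3)
  incl3 <- data.frame(channel_id = 1:3, included = c(TRUE, FALSE, TRUE))
  roi3 <- roi_average(ep2, probe2, incl3)
  expect_equal(roi3$value[roi3$hemisphere == "left"], 0.2)
})

test_that("ROI table size is bounded by the design combinatorics", {
  cfg <- quiet_config(sampling_rate_hz = 5,
                      group_sizes = c("LR" = 1, "HR-noASD" = 0,
                                      "HR-ASD" = 0), seed = 18)
  res <- cohort_responses(simulate_cohort(cfg))
  per_chromo <- nrow(res$roi_responses) / 2  # HbO2 and HHb
  expect_lte(per_chromo, 3 * 2 * 3 * 5)
  expect_equal(per_chromo, round(per_chromo))
})

test_that("vocal contrast is the vocal minus non-vocal difference", {
  roi <- data.frame(
    roi = "aMTG-STG", hemisphere = "left", chromophore = "HbO2",
    condition = rep(c("A-V", "A-NV"), each = 2),
    epoch = rep(c("8-12", "12-16"), 2),
    value = c(0.29, 0.29, -0.10, 0.29), n_channels = 1)
  d <- vocal_contrast(roi)
  expect_equal(d$difference[d$epoch == "8-12"], 0.39)
  expect_equal(d$difference[d$epoch == "12-16"], 0)
  # antisymmetry under swapping the condition labels
  roi_sw <- roi
  roi_sw$condition <- ifelse(roi$condition == "A-V", "A-NV", "A-V")
  d_sw <- vocal_contrast(roi_sw)
  expect_equal(d_sw$difference, -d$difference)
  # a missing condition leaves the cell absent
  expect_equal(nrow(vocal_contrast(roi[roi$condition == "A-V", ])), 0L)
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  # spec-style worked example
  p <- c(0.01, 0.02, 0.03, 0.2)
  adj <- stats::p.adjust(p, method = "BH")
  expect_identical(adj <= 0.05, bh_reject_oracle(p, 0.05))
  # all sorted p-vectors of length <= 8 over a fixed grid (BH decisions are
  # permutation-invariant, so sorted multisets cover every vector)
  grid <- c(0.001, 0.008, 0.01, 0.02, 0.04, 0.05, 0.2, 1)
  qs <- c(0.01, 0.05, 0.1, 0.25)
  mismatches <- 0L
  for (n in 1:8) {
    combos <- utils::combn(length(grid) + n - 1, n)
    for (j in seq_len(ncol(combos))) {
      p_vec <- grid[combos[, j] - seq_len(n) + 1]
      adj <- stats::p.adjust(p_vec, method = "BH")
      for (q in qs) {
        if (!identical(adj <= q, bh_reject_oracle(p_vec, q))) {
          mismatches <- mismatches + 1L
        }
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("channel-wise tests handle degenerate and paired inputs", {
  mk_peaks <- function(values, condition = "V-S") {
    do.call(rbind, lapply(seq_along(values), function(i) {
      data.frame(infant_id = sprintf("S%02d", i), channel_id = 1L,
                 condition = condition, chromophore = "HbO2",
                 window = "8-12", n_trials = 4L, peak = values[i])
    }))
  }
  # all peaks zero: t = 0 and p = 1 by convention
  res <- channelwise_tests(mk_peaks(rep(0, 6)), "visual")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # paired auditory contrast equals a one-sample test on the differences
  av <- mk_peaks(c(0.5, 0.7, 0.6, 0.9), "A-V")
  anv <- mk_peaks(c(0.1, 0.2, 0.4, 0.3), "A-NV")
  res_a <- channelwise_tests(rbind(av, anv), "auditory")
  ref <- stats::t.test(c(0.5, 0.7, 0.6, 0.9) - c(0.1, 0.2, 0.4, 0.3))
  expect_equal(res_a$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res_a$p, ref$p.value, tolerance = 1e-9)
  # single-infant channels are dropped and reported
  single <- mk_peaks(0.4)[1, ]
  res_s <- channelwise_tests(single, "visual")
  expect_equal(nrow(res_s), 0L)
  expect_equal(nrow(attr(res_s, "dropped")), 1L)
})

test_that("a truly active channel attains the smallest adjusted p", {
  set.seed(33)
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    peaks <- do.call(rbind, lapply(1:16, function(i) {
      data.frame(infant_id = sprintf("S%02d", i), channel_id = 1:8,
                 condition = "V-S", chromophore = "HbO2", window = "8-12",
                 n_trials = 4L,
                 peak = stats::rnorm(8, 0, 0.2) + c(0.6, rep(0, 7)))
    }))
    res <- channelwise_tests(peaks, "visual")
    if (which.min(res$p_fdr) == which(res$channel_id == 1)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})
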