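#' Looking-time trial validity
#'
#' A trial is valid if its coded looking proportion is strictly greater than
#' the threshold (default 0.60, i.e. more than 60% of the trial spent
#' looking). Trials with no looking code are invalid with reason
#' `"uncoded"`.
#'
#' @param looking `data.frame` with columns `trial_id` and `looking`
#'   (proportion in `[0, 1]`, `NA` for uncoded trials).
#' @param threshold Validity threshold (strict inequality).
#' @return `data.frame` with `trial_id`, `looking_valid`, `reason`.
#' @export
looking_validity <- function(looking, threshold = 0.60) {
  p <- looking$looking
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("looking proportions must lie in [0, 1]", call. = FALSE)
  }
  valid <- !is.na(p) & p > threshold
  reason <- rep(NA_character_, length(p))
  reason[is.na(p)] <- "uncoded"
  reason[!is.na(p) & p <= threshold] <- "insufficient_looking"
  data.frame(trial_id = looking$trial_id, looking_valid = valid,
             reason = reason, stringsAsFactors = FALSE)
}

#' Channel-level intensity artifact scan
#'
#' Classifies each channel of the raw recording as retained or rejected
#' using two explicit, thresholded rules applied to each wavelength's
#' intensity series: (a) the coefficient of variation exceeds `cv_max`, or
#' (b) the fraction of samples whose absolute deviation from a sliding-window
#' median, in robust-SD (MAD) units, exceeds `spike_z` is greater than
#' `frac_max`. A channel is rejected if either wavelength fails either rule.
#' A constant channel has zero coefficient of variation and no spikes, and
#' is retained.
#'
#' @param recording A [nirs_recording].
#' @param cv_max Maximum coefficient of variation.
#' @param spike_z Robust z-score above which a sample counts as a spike.
#' @param frac_max Maximum tolerated fraction of spike samples.
#' @param window_s Sliding-median window length in seconds.
#' @return `data.frame` with `channel_id`, `cv`, `spike_frac`,
#'   `intensity_artifact` (logical; `TRUE` = rejected).
#' @export
intensity_artifact_scan <- function(recording, cv_max = 0.10, spike_z = 5,
                                    frac_max = 0.02, window_s = 1) {
  fs <- recording$sampling_rate_hz
  k <- max(3L, round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  n_ch <- dim(recording$intensity)[1]
  cv <- numeric(n_ch)
  spike_frac <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    worst_cv <- 0
    worst_frac <- 0
    for (wl in 1:2) {
      x <- recording$intensity[ch, wl, ]
      worst_cv <- max(worst_cv, stats::sd(x) / mean(x))
      med <- stats::runmed(x, k)
      dev <- abs(x - med)
      rsd <- stats::mad(x - med)
      if (rsd > 0) {
        worst_frac <- max(worst_frac, mean(dev / rsd > spike_z))
      }
    }
    cv[ch] <- worst_cv
    spike_frac[ch] <- worst_frac
  }
  data.frame(channel_id = recording$channels$channel_id, cv = cv,
             spike_frac = spike_frac,
             intensity_artifact = cv > cv_max | spike_frac > frac_max)
}

#' Trial-level concentration artifact scan
#'
#' Second-level motion-artifact detection on the converted concentration
#' data: a trial is flagged for a channel when the absolute change in
#' oxy-haemoglobin concentration across any interval of `window_s` seconds
#' within the block strictly exceeds `jump_umol`. A change of exactly
#' `jump_umol` is not flagged (strict inequality).
#'
#' @param blocks A [preprocess_recording()] result.
#' @param jump_umol Concentration jump threshold in micromolar.
#' @param window_s Interval length in seconds.
#' @return `data.frame` with `channel_id`, `trial_id`, `max_jump_umol`,
#'   `concentration_artifact`.
#' @export
concentration_artifact_scan <- function(blocks, jump_umol = 1.0,
                                        window_s = 0.5) {
  fs <- blocks$sampling_rate_hz
  w <- max(1L, round(window_s * fs))
  n_ch <- nrow(blocks$channels)
  n_bl <- length(blocks$blocks)
  mj_all <- matrix(0, n_ch, n_bl)
  for (i in seq_len(n_bl)) {
    b <- blocks$blocks[[i]]
    n <- ncol(b$hbo)
    if (n <= w) next
    # max over lags 1..w of |x(t + lag) - x(t)|
    acc <- abs(b$hbo[, 2:n, drop = FALSE] - b$hbo[, 1:(n - 1), drop = FALSE])
    if (w > 1L) {
      for (lag in 2:w) {
        d <- abs(b$hbo[, (1 + lag):n, drop = FALSE] -
                   b$hbo[, 1:(n - lag), drop = FALSE])
        acc[, 1:(n - lag)] <- pmax(acc[, 1:(n - lag), drop = FALSE], d)
      }
    }
    mj_all[, i] <- acc[cbind(seq_len(n_ch),
                             max.col(acc, ties.method = "first"))]
  }
  quick_df(
    channel_id = rep(blocks$channels$channel_id, times = n_bl),
    trial_id = rep(vapply(blocks$blocks, function(b) b$trial_id, integer(1)),
                   each = n_ch),
    max_jump_umol = as.vector(mj_all),
    concentration_artifact = as.vector(mj_all) > jump_umol)
}

#' Assemble the per-trial validity ledger
#'
#' Combines the looking-time, channel-level intensity and trial-level
#' concentration flags into one row per channel x experimental trial. A
#' trial is valid on a channel iff no flag is set.
#'
#' @param blocks A [preprocess_recording()] result.
#' @param looking_flags Result of [looking_validity()].
#' @param intensity_flags Result of [intensity_artifact_scan()].
#' @param concentration_flags Result of [concentration_artifact_scan()].
#' @return `data.frame` with `channel_id`, `trial_id`, `condition`, the
#'   three flags, `incomplete_block` and `valid`.
#' @export
build_validity_ledger <- function(blocks, looking_flags, intensity_flags,
                                  concentration_flags) {
  trials <- data.frame(
    trial_id = vapply(blocks$blocks, function(b) b$trial_id, integer(1)),
    condition = vapply(blocks$blocks, function(b) b$condition, character(1)),
    incomplete_block = vapply(blocks$blocks, function(b) b$incomplete,
                              logical(1))
  )
  n_ch <- nrow(blocks$channels)
  n_tr <- nrow(trials)
  led <- quick_df(
    channel_id = rep(blocks$channels$channel_id, times = n_tr),
    trial_id = rep(trials$trial_id, each = n_ch),
    condition = rep(trials$condition, each = n_ch),
    incomplete_block = rep(trials$incomplete_block, each = n_ch))
  led$looking_invalid <- !looking_flags$looking_valid[
    match(led$trial_id, looking_flags$trial_id)]
  led$looking_invalid[is.na(led$looking_invalid)] <- TRUE
  led$intensity_artifact <- intensity_flags$intensity_artifact[
    match(led$channel_id, intensity_flags$channel_id)]
  key <- paste(led$channel_id, led$trial_id)
  ckey <- paste(concentration_flags$channel_id, concentration_flags$trial_id)
  led$concentration_artifact <- concentration_flags$concentration_artifact[
    match(key, ckey)]
  led$valid <- !led$looking_invalid & !led$intensity_artifact &
    !led$concentration_artifact & !led$incomplete_block
  led[order(led$channel_id, led$trial_id),
      c("channel_id", "trial_id", "condition", "looking_invalid",
        "intensity_artifact", "concentration_artifact", "incomplete_block",
        "valid")]
}

#' Apply the inclusion rules
#'
#' Finalizes the validity ledger for one infant:
#' \itemize{
#'   \item a channel is included iff it has at least `min_trials` valid
#'     trials in each of the three experimental conditions;
#'   \item the infant is included iff at least `min_trials` trials per
#'     condition are valid on at least one retained channel;
#'   \item an infant with no retained channel in either hemisphere's IFG ROI
#'     is additionally excluded from the visual analysis only.
#' }
#'
#' @param ledger Result of [build_validity_ledger()].
#' @param probe The probe map of the recording.
#' @param min_trials Minimum valid trials per condition (default 3).
#' @return List with `ledger`, `channels` (`channel_id`, `included`),
#'   `infant_included`, `visual_included`, and `reason` (`NA` when
#'   included).
#' @export
apply_inclusion_rules <- function(ledger, probe, min_trials = 3) {
  conds <- experimental_conditions()
  ch_ids <- sort(unique(ledger$channel_id))
  counts <- tapply(ledger$valid,
                   list(factor(ledger$channel_id, levels = ch_ids),
                        factor(ledger$condition, levels = conds)),
                   sum)
  counts[is.na(counts)] <- 0L
  included <- rowSums(counts >= min_trials) == length(conds)
  channels <- data.frame(channel_id = ch_ids, included = unname(included))

  retained <- ch_ids[included]
  on_retained <- ledger[ledger$channel_id %in% retained & ledger$valid, ,
                        drop = FALSE]
  per_cond <- vapply(conds, function(cc) {
    length(unique(on_retained$trial_id[on_retained$condition == cc]))
  }, integer(1))
  infant_included <- all(per_cond >= min_trials)

  ifg <- probe$channel_id[probe$roi == "IFG"]
  visual_included <- infant_included && any(retained %in% ifg)

  reason <- if (infant_included) {
    NA_character_
  } else if (length(retained) == 0L) {
    "no_valid_channels"
  } else {
    paste0("insufficient_valid_trials:",
           paste(conds[per_cond < min_trials], collapse = ","))
  }
  list(ledger = ledger, channels = channels,
       infant_included = infant_included,
       visual_included = visual_included, reason = reason)
}

#' Inclusion rate from study accounting counts
#'
#' @param n_tested Number of infants tested.
#' @param n_excluded Number excluded.
#' @return Included fraction `(n_tested - n_excluded) / n_tested`.
#' @export
inclusion_rate <- function(n_tested, n_excluded) {
  stopifnot(n_tested > 0, n_excluded >= 0, n_excluded <= n_tested)
  (n_tested - n_excluded) / n_tested
}

#' ASD recurrence rate among high-risk infants
#'
#' @param phenotypes Phenotype table with a `group` column using the labels
#'   of [outcome_groups()].
#' @return Fraction of high-risk infants (both HR groups) in the HR-ASD
#'   group.
#' @export
recurrence_rate <- function(phenotypes) {
  hr <- phenotypes$group %in% c("HR-noASD", "HR-ASD")
  if (!any(hr)) stop("no high-risk infants in the phenotype table",
                     call. = FALSE)
  sum(phenotypes$group == "HR-ASD") / sum(hr)
}
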