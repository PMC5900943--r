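#' Default group response amplitude table
#'
#' Encodes the group-level hemodynamic ground truth of the generator, in
#' micromolar, keyed by outcome group, condition, ROI and hemisphere.
#' Amplitudes are built from three components:
#' \itemize{
#'   \item a visual-social response in IFG and pSTS-TPJ (both hemispheres),
#'     present in every condition that shows social videos (all three), with
#'     group means decreasing from LR through HR-noASD to HR-ASD;
#'   \item a non-vocal auditory response in aMTG-STG and pSTS-TPJ (both
#'     hemispheres), equal across groups;
#'   \item a vocal-selectivity term added to the left-hemisphere auditory
#'     response of `A-V` trials: positive in LR, near zero in HR-noASD, and
#'     negative in HR-ASD, so the left-hemisphere vocal minus non-vocal
#'     difference carries the group ordering.
#' }
#' The columns `visual_w` and `vocal_w` mark where per-infant individual
#' deviations of the visual-social amplitude and of the vocal-selectivity
#' difference apply.
#'
#' @param visual_means Named visual-social amplitudes per group (uM).
#' @param vocal_diffs Named left-hemisphere vocal minus non-vocal differences
#'   per group (uM).
#' @param auditory_base Non-vocal auditory response amplitude (uM), common to
#'   all groups and hemispheres.
#' @return `data.frame` with columns `group`, `condition`, `roi`,
#'   `hemisphere`, `amplitude`, `visual_w`, `vocal_w`.
#' @export
default_amplitude_table <- function(
    visual_means = c("LR" = 0.45, "HR-noASD" = 0.28, "HR-ASD" = -0.053),
    vocal_diffs = c("LR" = 0.29, "HR-noASD" = 0.09, "HR-ASD" = -0.951),
    auditory_base = 0.40) {
  grid <- expand.grid(
    group = names(visual_means),
    condition = experimental_conditions(),
    roi = setdiff(roi_labels(), "none"),
    hemisphere = c("left", "right"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  visual_roi <- grid$roi %in% c("IFG", "pSTS-TPJ")
  auditory_roi <- grid$roi %in% c("aMTG-STG", "pSTS-TPJ")
  auditory_cond <- grid$condition %in% c("A-V", "A-NV")
  grid$visual_w <- as.numeric(visual_roi)
  grid$vocal_w <- as.numeric(grid$condition == "A-V" & auditory_roi &
                               grid$hemisphere == "left")
  grid$amplitude <- visual_roi * visual_means[grid$group] +
    (auditory_cond & auditory_roi) * auditory_base +
    grid$vocal_w * vocal_diffs[grid$group]
  rownames(grid) <- NULL
  grid
}

#' Physiological noise specification
#'
#' Additive noise on the chromophore concentrations, expressed in micromolar:
#' sinusoidal cardiac (default 2.2 Hz, the infant heart rate), respiratory
#' (0.6 Hz) and low-frequency vasomotor (0.1 Hz) oscillations with random
#' phase per channel, plus white noise. The cardiac and respiratory
#' components lie above the 1.7 Hz analysis low-pass or are strongly
#' attenuated by it; the 0.1 Hz component survives filtering and creates
#' realistic trial-to-trial variability.
#'
#' @param cardiac_amp,resp_amp,lowfreq_amp Oscillation amplitudes (uM).
#' @param cardiac_hz,resp_hz,lowfreq_hz Oscillation frequencies (Hz).
#' @param white_sd White-noise standard deviation per sample (uM).
#' @param enable Set `FALSE` for noise-free simulation.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_amp = 0.05, cardiac_hz = 2.2,
                       resp_amp = 0.05, resp_hz = 0.6,
                       lowfreq_amp = 0.10, lowfreq_hz = 0.1,
                       white_sd = 0.10, enable = TRUE) {
  structure(list(cardiac_amp = cardiac_amp, cardiac_hz = cardiac_hz,
                 resp_amp = resp_amp, resp_hz = resp_hz,
                 lowfreq_amp = lowfreq_amp, lowfreq_hz = lowfreq_hz,
                 white_sd = white_sd, enable = enable),
            class = "noise_spec")
}

#' Motion artifact specification
#'
#' Per-experimental-trial event probabilities for the two artifact kinds the
#' rejection stage must catch: brief high-amplitude spikes (a triangular
#' attenuation excursion equivalent to `spike_umol` of oxy-haemoglobin) and
#' persistent baseline shifts (a step of `shift_umol` equivalent). Events
#' affect all channels, emulating whole-head movement.
#'
#' @param spike_prob,shift_prob Per-trial event probabilities in `[0, 1]`.
#' @param spike_umol,shift_umol Event magnitudes (uM equivalent).
#' @param spike_dur_s Spike duration in seconds.
#' @param enable Set `FALSE` for artifact-free simulation.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(spike_prob = 0.02, spike_umol = 5, spike_dur_s = 0.4,
                          shift_prob = 0.01, shift_umol = 3, enable = TRUE) {
  stopifnot(spike_prob >= 0, spike_prob <= 1, shift_prob >= 0, shift_prob <= 1)
  structure(list(spike_prob = spike_prob, spike_umol = spike_umol,
                 spike_dur_s = spike_dur_s, shift_prob = shift_prob,
                 shift_umol = shift_umol, enable = enable),
            class = "artifact_spec")
}

#' Looking-time specification
#'
#' Per-trial looking proportion model: with probability `inattentive_prob`
#' the infant is inattentive for the trial and the looking proportion is
#' drawn from `Beta(inattentive_shape1, inattentive_shape2)` (mostly below
#' the 60% validity threshold); otherwise it is drawn from
#' `Beta(attentive_shape1, attentive_shape2)` (mean about 0.94, matching
#' reported looking times of included infants).
#'
#' @param inattentive_prob Probability of an inattentive trial in `[0, 1]`.
#' @param attentive_shape1,attentive_shape2 Beta parameters, attentive trials.
#' @param inattentive_shape1,inattentive_shape2 Beta parameters, inattentive
#'   trials.
#' @param fixed If not `NULL`, every trial gets this looking proportion
#'   (degenerate distribution; useful to disable attrition).
#' @return A list of class `looking_spec`.
#' @export
looking_spec <- function(inattentive_prob = 0.12,
                         attentive_shape1 = 60, attentive_shape2 = 4,
                         inattentive_shape1 = 2, inattentive_shape2 = 2,
                         fixed = NULL) {
  stopifnot(inattentive_prob >= 0, inattentive_prob <= 1)
  structure(list(inattentive_prob = inattentive_prob,
                 attentive_shape1 = attentive_shape1,
                 attentive_shape2 = attentive_shape2,
                 inattentive_shape1 = inattentive_shape1,
                 inattentive_shape2 = inattentive_shape2,
                 fixed = fixed),
            class = "looking_spec")
}

# Draw per-trial looking proportions from a looking_spec.
sample_looking <- function(spec, n_trials) {
  if (!is.null(spec$fixed)) return(rep(spec$fixed, n_trials))
  inattentive <- stats::runif(n_trials) < spec$inattentive_prob
  p <- stats::rbeta(n_trials, spec$attentive_shape1, spec$attentive_shape2)
  if (any(inattentive)) {
    p[inattentive] <- stats::rbeta(sum(inattentive), spec$inattentive_shape1,
                                   spec$inattentive_shape2)
  }
  p
}

#' Social Responsiveness Scale generation specification
#'
#' SRS totals are generated per group with the given means and standard
#' deviations, coupled to each infant's injected visual-social amplitude:
#' the standardized SRS is `coupling * z(amplitude)` plus independent noise,
#' so `coupling` is the population correlation between SRS and the injected
#' social response (negative by default: weaker social responses, higher
#' ASD-trait scores). With `group_only = TRUE`, SRS depends on group
#' membership alone.
#'
#' @param coupling Correlation in `[-1, 1]` between SRS and injected
#'   visual-social amplitude (within the standardized scale).
#' @param group_means,group_sds Named per-group SRS mean and SD.
#' @param group_only Generate SRS from group membership only.
#' @return A list of class `srs_spec`.
#' @export
srs_spec <- function(coupling = -0.5,
                     group_means = c("LR" = 21.57, "HR-noASD" = 21.07,
                                     "HR-ASD" = 77.8),
                     group_sds = c("LR" = 12.2, "HR-noASD" = 11.3,
                                   "HR-ASD" = 42.8),
                     group_only = FALSE) {
  stopifnot(coupling >= -1, coupling <= 1)
  structure(list(coupling = coupling, group_means = group_means,
                 group_sds = group_sds, group_only = group_only),
            class = "srs_spec")
}

#' Simulation configuration
#'
#' Assembles the full configuration of the synthetic cohort generator. The
#' defaults encode the study design being emulated: three outcome groups of
#' 16/15/5 infants, 26 channels at 2 cm separation measured at 770/850 nm
#' and 10 Hz, one 12-trial condition loop with interleaved reference trials,
#' group-ordered visual-social amplitudes, left-lateralized vocal
#' selectivity, physiological noise, motion artifacts, looking-time
#' attrition, and SRS scores negatively coupled to the social response.
#'
#' @param group_sizes Named counts per outcome group.
#' @param sampling_rate_hz Sampling rate (must exceed twice the 1.7 Hz
#'   analysis cutoff).
#' @param n_loops Number of 12-trial condition loops per infant.
#' @param probe Probe map (see [default_probe_map()]).
#' @param amplitudes Amplitude table (see [default_amplitude_table()]).
#' @param amplitude_reference `"window_mean"`: amplitudes are the mean clean
#'   response over the 8--16 s analysis window (the scale on which group
#'   means are reported); `"peak"`: amplitudes are the clean response maxima.
#' @param amplitude_sd Named per-infant deviation SDs, elements `social`
#'   (visual-social amplitude) and `vocal` (vocal minus non-vocal
#'   difference), in uM.
#' @param hhb_ratio Peak deoxy-haemoglobin change as a (negative) fraction of
#'   the oxy-haemoglobin change.
#' @param hrf List with `time_to_peak` and `shape` for [hrf_gamma()].
#' @param noise A [noise_spec()].
#' @param artifacts An [artifact_spec()].
#' @param looking A [looking_spec()].
#' @param srs An [srs_spec()].
#' @param mullen Named per-group list of `means` and `sds` for the Mullen
#'   Early Learning Composite standard score.
#' @param mbll [mbll_parameters()] used by the forward model (the same
#'   parameters the preprocessing stage inverts).
#' @param baseline_intensity Baseline light intensity (arbitrary units; the
#'   attenuation change is independent of its value).
#' @param trial_duration_sampler Passed to [build_stimulus_schedule()].
#' @param seed Integer seed; every random draw of the generator derives from
#'   it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c("LR" = 16, "HR-noASD" = 15,
                                       "HR-ASD" = 5),
                       sampling_rate_hz = 10,
                       n_loops = 1,
                       probe = default_probe_map(),
                       amplitudes = default_amplitude_table(),
                       amplitude_reference = c("window_mean", "peak"),
                       amplitude_sd = c(social = 0.30, vocal = 0.60),
                       hhb_ratio = -1 / 3,
                       hrf = list(time_to_peak = 7, shape = 8),
                       noise = noise_spec(),
                       artifacts = artifact_spec(),
                       looking = looking_spec(),
                       srs = srs_spec(),
                       mullen = list(
                         means = c("LR" = 122.47, "HR-noASD" = 112.53,
                                   "HR-ASD" = 89.4),
                         sds = c("LR" = 10.4, "HR-noASD" = 13.2,
                                 "HR-ASD" = 26.5)),
                       mbll = mbll_parameters(),
                       baseline_intensity = 1.0,
                       trial_duration_sampler = NULL,
                       seed = 1L) {
  amplitude_reference <- match.arg(amplitude_reference)
  if (sampling_rate_hz <= 2 * 1.7) {
    stop("sampling_rate_hz must exceed twice the 1.7 Hz analysis cutoff",
         call. = FALSE)
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  validate_probe_map(probe)
  structure(list(group_sizes = group_sizes,
                 sampling_rate_hz = sampling_rate_hz, n_loops = n_loops,
                 probe = probe, amplitudes = amplitudes,
                 amplitude_reference = amplitude_reference,
                 amplitude_sd = amplitude_sd, hhb_ratio = hhb_ratio,
                 hrf = hrf, noise = noise, artifacts = artifacts,
                 looking = looking, srs = srs, mullen = mullen, mbll = mbll,
                 baseline_intensity = baseline_intensity,
                 trial_duration_sampler = trial_duration_sampler,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a raw recording object
#'
#' @param intensity Numeric array `channels x 2 wavelengths x time` of
#'   strictly positive intensities (arbitrary units).
#' @param probe Probe map for the channels (rows match dim 1).
#' @param sampling_rate_hz Sampling rate.
#' @param meta Free-form provenance list.
#' @return Object of class `nirs_recording`.
#' @export
nirs_recording <- function(intensity, probe, sampling_rate_hz, meta = list()) {
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[2] == 2L)
  if (dim(intensity)[1] != nrow(probe)) {
    stop("intensity channel dimension must match probe map rows",
         call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    bad <- which(!(is.finite(intensity) & intensity > 0), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "intensity must be strictly positive and finite (channel %d, wavelength %s, sample %d)",
      probe$channel_id[bad[1]], c("770", "850")[bad[2]], bad[3]),
      call. = FALSE)
  }
  structure(list(intensity = intensity, channels = probe,
                 wavelengths_nm = c(770, 850),
                 sampling_rate_hz = sampling_rate_hz, meta = meta),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %d channels x 2 wavelengths x %d samples @ %g Hz\n",
              dim(x$intensity)[1], dim(x$intensity)[3], x$sampling_rate_hz))
  invisible(x)
}

#' Simulate one infant's recording
#'
#' Builds a clean concentration time course per channel (each experimental
#' trial's boxcar convolved with the gamma HRF, scaled by the amplitude table
#' entry for the channel's ROI and the infant's group plus the infant's
#' individual deviations), maps it through the forward modified Beer-Lambert
#' model to attenuation, exponentiates onto the baseline intensity, and adds
#' physiological noise and motion artifacts. All injected quantities are
#' logged in the returned ground truth.
#'
#' @param config A [sim_config()].
#' @param group Outcome group label present in the amplitude table.
#' @param schedule Schedule from [build_stimulus_schedule()]; must be
#'   non-empty.
#' @param seed Integer seed for this infant's draws.
#' @return List with elements `recording` ([nirs_recording]), `looking`
#'   (data.frame `trial_id`, `looking`), and `truth` (list: `group`,
#'   `amplitudes` per condition x ROI x hemisphere, `social_amplitude`,
#'   `vocal_diff`, `artifacts` event log, `looking`).
#' @export
simulate_infant <- function(config, group, schedule, seed = 1L) {
  if (!group %in% unique(config$amplitudes$group)) {
    stop("unknown group: ", group, call. = FALSE)
  }
  if (nrow(schedule) == 0L) stop("schedule is empty", call. = FALSE)
  fs <- config$sampling_rate_hz
  if (fs <= 2 * 1.7) {
    stop("sampling rate incompatible with the 1.7 Hz analysis cutoff",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  probe <- config$probe
  n_ch <- nrow(probe)
  total_s <- max(schedule$onset_s + schedule$duration_s) + 3
  n_t <- floor(total_s * fs) + 1L

  # per-infant deviations
  d_social <- stats::rnorm(1, 0, config$amplitude_sd[["social"]])
  d_vocal <- stats::rnorm(1, 0, config$amplitude_sd[["vocal"]])

  amp <- config$amplitudes[config$amplitudes$group == group, , drop = FALSE]
  amp$amplitude <- amp$amplitude + d_social * amp$visual_w +
    d_vocal * amp$vocal_w

  # amplitude matrix channels x conditions
  conds <- experimental_conditions()
  a_mat <- matrix(0, n_ch, length(conds), dimnames = list(NULL, conds))
  key_amp <- paste(amp$condition, amp$roi, amp$hemisphere)
  for (j in seq_along(conds)) {
    key_ch <- paste(conds[j], probe$roi, probe$hemisphere)
    hit <- match(key_ch, key_amp)
    a_mat[, j] <- ifelse(is.na(hit), 0, amp$amplitude[hit])
  }

  resp <- vapply(conds, function(cc) {
    condition_response(schedule, cc, fs, n_t, config$hrf,
                       config$amplitude_reference)
  }, numeric(n_t))
  if (config$amplitude_reference == "window_mean") {
    # place amplitudes on the measurement scale exactly: compensate the
    # inter-trial response carry-over quantified by the cross-measurement
    # matrix, so the noise-free pipeline read-out equals the table entries
    M <- measurement_matrix(schedule, fs, n_t, config$hrf, R = t(resp))
    a_mat <- a_mat %*% t(solve(M))
  }
  hbo <- a_mat %*% t(resp)              # channels x time
  hhb <- config$hhb_ratio * hbo

  if (isTRUE(config$noise$enable)) {
    ns <- config$noise
    tt <- (seq_len(n_t) - 1L) / fs
    for (chromo in c("hbo", "hhb")) {
      scale <- if (chromo == "hbo") 1 else abs(config$hhb_ratio)
      phases <- matrix(stats::runif(3L * n_ch, 0, 2 * pi), n_ch, 3L)
      osc <- ns$cardiac_amp * sin(outer(phases[, 1], 2 * pi * ns$cardiac_hz * tt, `+`)) +
        ns$resp_amp * sin(outer(phases[, 2], 2 * pi * ns$resp_hz * tt, `+`)) +
        ns$lowfreq_amp * sin(outer(phases[, 3], 2 * pi * ns$lowfreq_hz * tt, `+`))
      wn <- matrix(stats::rnorm(n_ch * n_t, 0, ns$white_sd), n_ch, n_t)
      if (chromo == "hbo") hbo <- hbo + scale * (osc + wn)
      else hhb <- hhb + scale * (osc + wn)
    }
  }

  att <- mbll_forward(hbo, hhb, config$mbll)

  # motion artifacts added in the attenuation domain (equivalently,
  # multiplicative events on intensity), affecting all channels
  artifact_log <- data.frame(trial_id = integer(0), kind = character(0),
                             sample = integer(0), magnitude_umol = numeric(0))
  if (isTRUE(config$artifacts$enable)) {
    ar <- config$artifacts
    exp_tr <- experimental_trials(schedule)
    pl <- config$mbll$separation_cm * config$mbll$dpf
    e770 <- config$mbll$extinction["770", "HbO2"]
    e850 <- config$mbll$extinction["850", "HbO2"]
    for (i in seq_len(nrow(exp_tr))) {
      if (stats::runif(1) < ar$spike_prob) {
        s0 <- round(exp_tr$onset_s[i] * fs) +
          sample.int(max(1L, round(exp_tr$duration_s[i] * fs)), 1L)
        half <- max(1L, round(ar$spike_dur_s * fs / 2))
        w <- 1 - abs(seq(-half, half)) / (half + 1)  # triangular pulse
        idx <- s0 + seq(-half, half)
        keep <- idx >= 1L & idx <= n_t
        pulse <- ar$spike_umol * w[keep]
        att$a770[, idx[keep]] <- att$a770[, idx[keep]] +
          rep(e770 * pl * pulse, each = n_ch)
        att$a850[, idx[keep]] <- att$a850[, idx[keep]] +
          rep(e850 * pl * pulse, each = n_ch)
        artifact_log <- rbind(artifact_log, data.frame(
          trial_id = exp_tr$trial_id[i], kind = "spike", sample = s0,
          magnitude_umol = ar$spike_umol))
      }
      if (stats::runif(1) < ar$shift_prob) {
        s0 <- round(exp_tr$onset_s[i] * fs) +
          sample.int(max(1L, round(exp_tr$duration_s[i] * fs)), 1L)
        idx <- s0:n_t
        att$a770[, idx] <- att$a770[, idx] + e770 * pl * ar$shift_umol
        att$a850[, idx] <- att$a850[, idx] + e850 * pl * ar$shift_umol
        artifact_log <- rbind(artifact_log, data.frame(
          trial_id = exp_tr$trial_id[i], kind = "baseline_shift", sample = s0,
          magnitude_umol = ar$shift_umol))
      }
    }
  }

  intensity <- array(0, dim = c(n_ch, 2L, n_t))
  intensity[, 1L, ] <- config$baseline_intensity * 10^(-att$a770)
  intensity[, 2L, ] <- config$baseline_intensity * 10^(-att$a850)
  rec <- nirs_recording(intensity, probe, fs,
                        meta = list(group = group, seed = as.integer(seed)))

  exp_tr <- experimental_trials(schedule)
  looking <- data.frame(trial_id = exp_tr$trial_id,
                        looking = sample_looking(config$looking,
                                                 nrow(exp_tr)))

  visual_rows <- amp$condition == "V-S" & amp$visual_w > 0
  truth <- list(
    group = group,
    amplitudes = amp[, c("condition", "roi", "hemisphere", "amplitude")],
    social_amplitude = mean(amp$amplitude[visual_rows]),
    vocal_diff = amp$amplitude[amp$vocal_w > 0][1] -
      amp$amplitude[amp$condition == "A-NV" & amp$roi == "aMTG-STG" &
                      amp$hemisphere == "left"][1],
    artifacts = artifact_log,
    looking = looking$looking
  )
  list(recording = rec, looking = looking, truth = truth)
}

#' Simulate a cohort
#'
#' Generates one recording, looking record, schedule and ground truth per
#' infant, plus a phenotype table with outcome group, SRS total (coupled to
#' the injected visual-social amplitude per the configuration), Mullen ELC
#' standard score and age. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `infants` (list of per-infant lists with elements
#'   `schedule`, `recording`, `looking`, `truth`), `phenotypes`
#'   (data.frame), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  sizes <- config$group_sizes[config$group_sizes > 0]
  groups <- rep(names(sizes), times = sizes)
  n <- length(groups)
  if (n == 0L) stop("all group sizes are zero", call. = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, 2L * n + 1L)

  infants <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- build_stimulus_schedule(config$n_loops,
                                     config$trial_duration_sampler,
                                     seed = seeds[2L * i - 1L])
    sim <- simulate_infant(config, groups[i], sched, seed = seeds[2L * i])
    infants[[i]] <- list(schedule = sched, recording = sim$recording,
                         looking = sim$looking, truth = sim$truth)
  }

  set.seed(seeds[2L * n + 1L])
  social <- vapply(infants, function(x) x$truth$social_amplitude, numeric(1))
  z <- if (n > 1L && stats::sd(social) > 0) {
    as.numeric(scale(social))
  } else {
    numeric(n)
  }
  sp <- config$srs
  cpl <- if (isTRUE(sp$group_only)) 0 else sp$coupling
  srs_z <- cpl * z + sqrt(1 - cpl^2) * stats::rnorm(n)
  srs <- sp$group_means[groups] + sp$group_sds[groups] * srs_z
  mullen <- config$mullen$means[groups] +
    config$mullen$sds[groups] * stats::rnorm(n)
  phenotypes <- data.frame(
    infant_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    srs_total = as.numeric(srs),
    mullen_elc = as.numeric(mullen),
    age_months = stats::runif(n, 4, 6),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) infants[[i]]$infant_id <- phenotypes$infant_id[i]
  list(infants = infants, phenotypes = phenotypes, config = config)
}
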