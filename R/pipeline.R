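#' Analysis options
#'
#' Bundles every tunable threshold of the preprocessing and rejection
#' stages, so one object travels through the pipeline and into the run
#' manifest.
#'
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param mbll [mbll_parameters()].
#' @param looking_threshold Looking-time validity threshold (strict).
#' @param min_trials Minimum valid trials per condition.
#' @param cv_max,spike_z,spike_frac_max,spike_window_s Channel-level
#'   intensity scan thresholds (see [intensity_artifact_scan()]).
#' @param jump_umol,jump_window_s Trial-level concentration scan thresholds
#'   (see [concentration_artifact_scan()]).
#' @return A list of class `analysis_options`.
#' @export
analysis_options <- function(cutoff_hz = 1.7, mbll = mbll_parameters(),
                             looking_threshold = 0.60, min_trials = 3,
                             cv_max = 0.10, spike_z = 5,
                             spike_frac_max = 0.02, spike_window_s = 1,
                             jump_umol = 1.0, jump_window_s = 0.5) {
  structure(list(cutoff_hz = cutoff_hz, mbll = mbll,
                 looking_threshold = looking_threshold,
                 min_trials = min_trials, cv_max = cv_max, spike_z = spike_z,
                 spike_frac_max = spike_frac_max,
                 spike_window_s = spike_window_s, jump_umol = jump_umol,
                 jump_window_s = jump_window_s),
            class = "analysis_options")
}

#' Process one infant's recording
#'
#' Runs preprocessing, the two-level rejection scheme, trial averaging,
#' windowed peaks, epoch summaries and ROI averaging for a single infant.
#'
#' @param recording A [nirs_recording].
#' @param schedule The infant's stimulus schedule.
#' @param looking The infant's looking record (`trial_id`, `looking`).
#' @param options [analysis_options()].
#' @param peaks Compute channel-wise windowed peaks (set `FALSE` to skip
#'   them when only ROI-level statistics are needed).
#' @param chromophores Chromophores carried into the epoch and ROI
#'   summaries.
#' @return List with `ledger`, `inclusion`, `average`, `peaks`, `epochs`,
#'   `roi_responses`, `differences`.
#' @export
infant_responses <- function(recording, schedule, looking,
                             options = analysis_options(), peaks = TRUE,
                             chromophores = c("HbO2", "HHb")) {
  blocks <- preprocess_recording(recording, schedule, options$mbll,
                                 options$cutoff_hz)
  lk <- looking_validity(looking, options$looking_threshold)
  intens <- intensity_artifact_scan(recording, options$cv_max,
                                    options$spike_z, options$spike_frac_max,
                                    options$spike_window_s)
  conc <- concentration_artifact_scan(blocks, options$jump_umol,
                                      options$jump_window_s)
  ledger <- build_validity_ledger(blocks, lk, intens, conc)
  inclusion <- apply_inclusion_rules(ledger, recording$channels,
                                     options$min_trials)
  avg <- average_trials(blocks, ledger, options$min_trials)
  pk <- if (peaks) window_peaks(avg) else NULL
  epochs <- epoch_summaries(avg, chromophores)
  roi <- roi_average(epochs, recording$channels, inclusion$channels)
  diffs <- vocal_contrast(roi)
  list(ledger = ledger, inclusion = inclusion, average = avg, peaks = pk,
       epochs = epochs, roi_responses = roi, differences = diffs)
}

#' Process a simulated cohort
#'
#' Applies [infant_responses()] to every infant of a [simulate_cohort()]
#' result and stacks the per-infant tables, joining outcome groups from the
#' phenotype table. Infants failing the inclusion rules contribute only to
#' the accounting.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param options [analysis_options()].
#' @param peaks Compute channel-wise windowed peaks.
#' @param chromophores Chromophores carried into the epoch and ROI
#'   summaries.
#' @return List with stacked `roi_responses`, `differences`, `peaks`,
#'   `ledgers`, per-infant `inclusion` table, and `phenotypes`.
#' @export
cohort_responses <- function(cohort, options = analysis_options(),
                             peaks = TRUE,
                             chromophores = c("HbO2", "HHb")) {
  ph <- cohort$phenotypes
  roi_all <- list(); diff_all <- list(); peaks_all <- list()
  ledger_all <- list()
  incl <- data.frame(infant_id = ph$infant_id, group = ph$group,
                     included = FALSE, visual_included = FALSE,
                     reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(cohort$infants)) {
    inf <- cohort$infants[[i]]
    res <- infant_responses(inf$recording, inf$schedule, inf$looking,
                            options, peaks = peaks,
                            chromophores = chromophores)
    incl$included[i] <- res$inclusion$infant_included
    incl$visual_included[i] <- res$inclusion$visual_included
    incl$reason[i] <- res$inclusion$reason
    led <- res$ledger
    led$infant_id <- inf$infant_id
    ledger_all[[i]] <- led
    if (!res$inclusion$infant_included) next
    add_id <- function(d) {
      if (nrow(d) == 0L) return(d)
      d$infant_id <- inf$infant_id
      d$group <- ph$group[i]
      d
    }
    roi <- add_id(res$roi_responses)
    if (!res$inclusion$visual_included && nrow(roi) > 0L) {
      roi <- roi[roi$condition != "V-S", , drop = FALSE]
    }
    roi_all[[i]] <- roi
    diff_all[[i]] <- add_id(res$differences)
    if (peaks) peaks_all[[i]] <- add_id(res$peaks)
  }
  bind <- function(lst) {
    lst <- Filter(function(d) !is.null(d) && nrow(d) > 0L, lst)
    if (length(lst) == 0L) NULL else do.call(rbind, lst)
  }
  list(roi_responses = bind(roi_all), differences = bind(diff_all),
       peaks = bind(peaks_all), ledgers = bind(ledger_all),
       inclusion = incl, phenotypes = ph)
}

#' Analyze a cohort end-to-end
#'
#' Runs [cohort_responses()] and, where the data allow, the channel-wise
#' tests, the visual and auditory mixed models, and the SRS correlations.
#' Stages that cannot run (e.g. a group lost entirely to attrition) are
#' `NULL` with the reason recorded in `notes`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param options [analysis_options()].
#' @return List with `responses`, `channel_stats` (visual + auditory),
#'   `visual_model`, `auditory_model`, `srs`, `notes`.
#' @export
analyze_cohort <- function(cohort, options = analysis_options()) {
  resp <- cohort_responses(cohort, options)
  notes <- character(0)
  channel_stats <- NULL
  visual_model <- NULL
  auditory_model <- NULL
  srs <- NULL
  if (!is.null(resp$peaks)) {
    channel_stats <- rbind(
      cbind(contrast = "visual", channelwise_tests(resp$peaks, "visual")),
      cbind(contrast = "auditory", channelwise_tests(resp$peaks, "auditory")))
  }
  if (!is.null(resp$roi_responses)) {
    visual_model <- tryCatch(fit_visual_model(resp$roi_responses),
                             error = function(e) {
                               notes <<- c(notes, paste("visual model:",
                                                        conditionMessage(e)))
                               NULL
                             })
  }
  if (!is.null(resp$differences)) {
    auditory_model <- tryCatch(fit_auditory_model(resp$differences),
                               error = function(e) {
                                 notes <<- c(notes, paste("auditory model:",
                                                          conditionMessage(e)))
                                 NULL
                               })
  }
  if (!is.null(resp$roi_responses) && !is.null(resp$differences)) {
    pred <- srs_predictors(resp$roi_responses, resp$differences)
    srs <- correlate_srs(pred, resp$phenotypes)
  }
  list(responses = resp, channel_stats = channel_stats,
       visual_model = visual_model, auditory_model = auditory_model,
       srs = srs, notes = notes)
}

#' Run the full pipeline
#'
#' Simulate a cohort, analyze it, and write all result tables plus a
#' reproducibility manifest to `out_dir`. Identical configuration and seed
#' give identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param options [analysis_options()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, the [analyze_cohort()] result.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         options = analysis_options(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  analysis <- analyze_cohort(cohort, options)
  resp <- analysis$responses

  tables <- list(
    phenotypes = resp$phenotypes,
    inclusion = resp$inclusion,
    validity_ledger = if (is.null(resp$ledgers)) data.frame() else resp$ledgers,
    roi_responses = if (is.null(resp$roi_responses)) data.frame() else
      resp$roi_responses,
    differences = if (is.null(resp$differences)) data.frame() else
      resp$differences,
    channel_stats = if (is.null(analysis$channel_stats)) data.frame() else
      analysis$channel_stats
  )
  if (!is.null(analysis$visual_model)) {
    tables$visual_anova <- analysis$visual_model$anova
    tables$visual_means <- analysis$visual_model$group_means
    tables$visual_pairwise <- analysis$visual_model$pairwise
  }
  if (!is.null(analysis$auditory_model)) {
    tables$auditory_anova <- analysis$auditory_model$anova
    tables$auditory_means <- analysis$auditory_model$group_means
    tables$auditory_cell_contrasts <- analysis$auditory_model$cell_contrasts
  }
  n <- nrow(resp$phenotypes)
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    options_hash = config_hash(options),
    counts = list(
      infants_simulated = n,
      infants_included = sum(resp$inclusion$included),
      infants_visual = sum(resp$inclusion$visual_included),
      inclusion_rate = inclusion_rate(n, n - sum(resp$inclusion$included))
    ),
    notes = analysis$notes
  )
  write_results(tables, out_dir, manifest)
  invisible(analysis)
}
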