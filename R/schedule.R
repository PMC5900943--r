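#' Condition loop used for stimulus presentation
#'
#' The twelve-trial pseudo-random loop in which the three experimental
#' conditions are presented: visual social (`"V-S"`), auditory vocal with
#' concurrent visual social (`"A-V"`), and auditory non-vocal with concurrent
#' visual social (`"A-NV"`). Each loop contains every condition four times.
#'
#' @return Character vector of length 12 with condition labels.
#' @export
condition_loop <- function() {
  c("V-S", "A-NV", "A-V", "V-S", "A-V", "A-NV",
    "V-S", "A-V", "A-NV", "V-S", "A-NV", "A-V")
}

#' Experimental condition and group label sets
#'
#' @return Character vectors of the experimental condition labels and the
#'   outcome group labels used throughout the package.
#' @export
experimental_conditions <- function() c("V-S", "A-V", "A-NV")

#' @rdname experimental_conditions
#' @export
outcome_groups <- function() c("LR", "HR-noASD", "HR-ASD")

#' Build a stimulus schedule
#'
#' Constructs the alternating sequence of reference and experimental trials:
#' a reference trial (silent static non-social images) precedes, separates,
#' and follows the experimental trials, whose conditions follow
#' [condition_loop()] repeated `n_loops` times. Trial durations are drawn
#' from `trial_duration_sampler` (default: uniform on 9--12 s, the video
#' presentation range); auditory stimuli within `A-V`/`A-NV` trials span
#' exactly 8 s from trial onset.
#'
#' @param n_loops Number of 12-trial condition loops (non-negative integer).
#' @param trial_duration_sampler Function `n -> n durations in seconds`;
#'   defaults to `runif(n, 9, 12)`. Used for both experimental and reference
#'   trials.
#' @param seed Optional integer seed for the duration draws.
#' @return A `data.frame` of class `nirs_schedule` with columns `trial_id`,
#'   `condition` (`"REF"`, `"V-S"`, `"A-V"`, `"A-NV"`), `onset_s`,
#'   `duration_s`, and `auditory_span_s` (8 for auditory trials, `NA`
#'   otherwise). Zero rows when `n_loops = 0`.
#' @export
build_stimulus_schedule <- function(n_loops,
                                    trial_duration_sampler = NULL,
                                    seed = NULL) {
  if (length(n_loops) != 1L || is.na(n_loops) || n_loops < 0 ||
      n_loops != floor(n_loops)) {
    stop("`n_loops` must be a single non-negative integer", call. = FALSE)
  }
  if (is.null(trial_duration_sampler)) {
    trial_duration_sampler <- function(n) stats::runif(n, 9, 12)
  }
  if (!is.null(seed)) set.seed(seed)

  conditions <- rep(condition_loop(), times = n_loops)
  n_exp <- length(conditions)
  if (n_exp == 0L) {
    sched <- data.frame(trial_id = integer(0), condition = character(0),
                        onset_s = numeric(0), duration_s = numeric(0),
                        auditory_span_s = numeric(0))
    class(sched) <- c("nirs_schedule", "data.frame")
    return(sched)
  }
  # REF, E1, REF, E2, ..., E_n, REF
  all_cond <- character(2L * n_exp + 1L)
  all_cond[seq(1L, length(all_cond), by = 2L)] <- "REF"
  all_cond[seq(2L, length(all_cond), by = 2L)] <- conditions
  durations <- trial_duration_sampler(length(all_cond))
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("trial durations must be finite and positive", call. = FALSE)
  }
  onsets <- cumsum(c(0, durations[-length(durations)]))
  sched <- data.frame(
    trial_id = seq_along(all_cond),
    condition = all_cond,
    onset_s = onsets,
    duration_s = durations,
    auditory_span_s = ifelse(all_cond %in% c("A-V", "A-NV"), 8, NA_real_),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("nirs_schedule", "data.frame")
  sched
}

#' Validate a stimulus schedule
#'
#' Checks the structural invariants of a schedule: strictly increasing,
#' non-overlapping trials and reference trials separating consecutive
#' experimental trials.
#'
#' @param schedule A schedule as returned by [build_stimulus_schedule()].
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  req <- c("trial_id", "condition", "onset_s", "duration_s")
  if (!all(req %in% names(schedule))) {
    stop("schedule is missing columns: ",
         paste(setdiff(req, names(schedule)), collapse = ", "), call. = FALSE)
  }
  if (nrow(schedule) == 0L) return(invisible(schedule))
  ends <- schedule$onset_s + schedule$duration_s
  if (any(diff(schedule$onset_s) <= 0)) {
    stop("trial onsets must be strictly increasing", call. = FALSE)
  }
  if (any(ends[-length(ends)] > schedule$onset_s[-1] + 1e-9)) {
    stop("trials overlap", call. = FALSE)
  }
  is_exp <- schedule$condition != "REF"
  idx <- which(is_exp)
  if (length(idx) > 1L && any(diff(idx) < 2L)) {
    stop("experimental trials must be separated by reference trials",
         call. = FALSE)
  }
  invisible(schedule)
}

#' Index experimental trials in a schedule
#'
#' @param schedule A schedule.
#' @return The rows of `schedule` that are experimental (non-reference)
#'   trials.
#' @export
experimental_trials <- function(schedule) {
  schedule[schedule$condition != "REF", , drop = FALSE]
}
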