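#' Single-gamma hemodynamic response function
#'
#' A gamma-variate impulse response normalized to unit peak, with peak at
#' `time_to_peak` seconds. With the default shape the kernel has standard
#' deviation `time_to_peak / sqrt(shape - 1)` of roughly 2.6 s, so that the
#' response to a 9--12 s stimulus peaks towards the end of, or just beyond,
#' the trial -- inside the 8--16 s analysis windows.
#'
#' @param t Time in seconds (vector, `t >= 0`; negative values return 0).
#' @param time_to_peak Peak latency in seconds (default 7).
#' @param shape Gamma shape parameter `> 1` (default 8).
#' @return Values of the kernel at `t`, max 1 at `t = time_to_peak`.
#' @export
hrf_gamma <- function(t, time_to_peak = 7, shape = 8) {
  stopifnot(time_to_peak > 0, shape > 1)
  scale <- time_to_peak / (shape - 1)
  h <- numeric(length(t))
  pos <- which(t > 0)
  h[pos] <- (t[pos] / time_to_peak)^(shape - 1) *
    exp(-(t[pos] - time_to_peak) / scale)
  h
}

# Clean unit-amplitude response time course for one condition of a schedule.
# Each experimental trial contributes its stimulus boxcar convolved with the
# HRF, normalized per trial so the amplitude parameter has a well-defined
# measurement meaning:
#   "peak"        -- the maximum of the clean response equals 1;
#   "window_mean" -- after applying the same block detrend and onset
#                    baseline correction the analysis applies, the average
#                    of the 8-12 s and 12-16 s epoch means equals 1, i.e.
#                    the amplitude is expressed on the scale on which the
#                    pipeline reports responses.
# Returns a vector over the full recording grid.
condition_response <- function(schedule, condition, fs, n_samples,
                               hrf = list(time_to_peak = 7, shape = 8),
                               amplitude_reference = c("window_mean", "peak")) {
  amplitude_reference <- match.arg(amplitude_reference)
  out <- numeric(n_samples)
  trials <- schedule[schedule$condition == condition, , drop = FALSE]
  if (nrow(trials) == 0L) return(out)
  # HRF sampled until it has decayed to < 1e-9 of peak (capped at 40 s)
  t_h <- seq(0, 40, by = 1 / fs)
  h <- hrf_gamma(t_h, hrf$time_to_peak, hrf$shape)
  keep <- max(which(h > 1e-9 * max(h)))
  h <- h[seq_len(keep)]
  for (i in seq_len(nrow(trials))) {
    n_box <- max(1L, round(trials$duration_s[i] * fs))
    shape_t <- stats::convolve(c(rep(1, n_box), numeric(length(h))),
                               rev(h), type = "open")
    shape_t <- shape_t[seq_len(n_box + length(h) - 1L)]
    if (amplitude_reference == "peak") {
      norm <- max(shape_t)
    } else {
      # replicate the block the analysis will cut around this trial:
      # 4 s pre-onset, out to max(20 s, trial + following REF trial)
      row <- which(schedule$trial_id == trials$trial_id[i])
      ref_dur <- if (row < nrow(schedule) &&
                     schedule$condition[row + 1L] == "REF") {
        schedule$duration_s[row + 1L]
      } else {
        20 - trials$duration_s[i]
      }
      end_s <- max(20, trials$duration_s[i] + ref_dur)
      rel <- seq.int(-round(4 * fs), round(end_s * fs)) / fs
      sb <- numeric(length(rel))
      pos <- which(rel >= -1e-9)
      take <- seq_len(min(length(pos), length(shape_t)))
      sb[pos[take]] <- shape_t[take]
      db <- detrend_block(sb, rel)
      db <- db - mean(db[rel >= -1e-9 & rel <= 0.1 + 1e-9])
      e1 <- mean(db[rel >= 8 - 1e-9 & rel <= 12 + 1e-9])
      e2 <- mean(db[rel >= 12 - 1e-9 & rel <= 16 + 1e-9])
      norm <- (e1 + e2) / 2
    }
    if (!is.finite(norm) || norm <= 0) {
      stop("degenerate response shape; check HRF parameters and durations",
           call. = FALSE)
    }
    shape_t <- shape_t / norm
    onset_idx <- round(trials$onset_s[i] * fs) + 1L
    idx <- onset_idx:min(n_samples, onset_idx + length(shape_t) - 1L)
    if (idx[1] > n_samples) next
    out[idx] <- out[idx] + shape_t[seq_along(idx)]
  }
  out
}

# Condition cross-measurement matrix of a schedule. Entry [c_meas, c_src] is
# the value the analysis chain (block segmentation, linear detrend, onset
# baseline correction, average of the 8-12 and 12-16 s epoch means, averaged
# over the complete blocks of c_meas) reads out of the unit-amplitude clean
# response series of condition c_src. The diagonal is ~1 by construction of
# condition_response(); off-diagonal terms quantify inter-trial response
# carry-over. Used by the simulator to place injected amplitudes on the
# measurement scale exactly: injecting solve(M) %*% target makes the
# noise-free pipeline read-out equal the target.
measurement_matrix <- function(schedule, fs, n_samples,
                               hrf = list(time_to_peak = 7, shape = 8),
                               R = NULL) {
  conds <- experimental_conditions()
  if (is.null(R)) {
    R <- t(vapply(conds, function(cc) {
      condition_response(schedule, cc, fs, n_samples, hrf, "window_mean")
    }, numeric(n_samples)))
  }
  blocks <- segment_blocks(R, schedule, fs)
  M <- diag(3)
  dimnames(M) <- list(conds, conds)
  tol <- 1e-9
  for (cm in conds) {
    bl <- Filter(function(b) b$condition == cm && !b$incomplete, blocks)
    if (length(bl) == 0L) next
    vals <- vapply(bl, function(b) {
      db <- detrend_block(b$data, b$rel_time)
      rel <- b$rel_time
      corr <- rowMeans(db[, rel >= -tol & rel <= 0.1 + tol, drop = FALSE])
      e1 <- rowMeans(db[, rel >= 8 - tol & rel <= 12 + tol, drop = FALSE])
      e2 <- rowMeans(db[, rel >= 12 - tol & rel <= 16 + tol, drop = FALSE])
      (e1 + e2) / 2 - corr
    }, numeric(3))
    M[cm, ] <- rowMeans(vals)
  }
  M
}
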