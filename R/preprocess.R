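#' Convert intensity to attenuation change
#'
#' Attenuation change is `-log10(I(t) / I_ref)` with `I_ref` the mean
#' intensity of each channel-wavelength series. Any constant reference
#' choice only shifts the attenuation by a constant, which the detrending
#' and baseline-correction stages remove.
#'
#' @param recording A [nirs_recording].
#' @return Array `channels x 2 wavelengths x time` of attenuation changes
#'   (dimensionless).
#' @export
intensity_to_attenuation <- function(recording) {
  x <- recording$intensity
  if (any(x <= 0)) stop("intensity must be strictly positive", call. = FALSE)
  ref <- apply(x, c(1, 2), mean)
  -log10(x / as.vector(ref))
}

#' Zero-phase low-pass filter
#'
#' 5th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the pass band has unit gain and zero phase shift -- response timing is
#' preserved for the onset-locked analysis windows.
#'
#' @param x Numeric vector, or matrix with one series per row.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency (default 1.7 Hz); must be below the
#'   Nyquist frequency.
#' @param order Filter order.
#' @return Filtered data, same shape as `x`.
#' @export
lowpass <- function(x, fs, cutoff_hz = 1.7, order = 5) {
  if (cutoff_hz >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  if (is.matrix(x)) {
    t(filtfilt_mat(bf$b, bf$a, t(x)))
  } else {
    as.numeric(filtfilt_mat(bf$b, bf$a, matrix(x, ncol = 1)))
  }
}

# One-pass IIR filter of every column of x (zero initial conditions),
# direct form: y[n] = sum(b * x[n - k]) - sum(a[-1] * y[n - k]).
iir_filter_mat <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1L) {
    u <- stats::filter(rbind(matrix(0, nb - 1L, ncol(x)), x), b,
                       method = "convolution", sides = 1)
    u <- u[-seq_len(nb - 1L), , drop = FALSE]
  } else {
    u <- b * x
  }
  y <- stats::filter(u, -a[-1] / a[1], method = "recursive") / a[1]
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# Zero-phase (forward-backward) filtering of every column of x. Both ends
# are padded with the odd reflection of the signal (2*x[end] - x) so that
# the startup transients of the two passes die out in the padding; a
# constant series passes through exactly (unit DC gain).
filtfilt_mat <- function(b, a, x) {
  n <- nrow(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  pre <- 2 * x[rep(1L, pad), , drop = FALSE] -
    x[(pad + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(n, pad), , drop = FALSE] -
    x[(n - 1L):(n - pad), , drop = FALSE]
  g <- sum(b) / sum(a)  # DC gain
  pass <- function(z) {
    # referencing each series to its first value removes the step the zero
    # initial conditions would otherwise see at the start of the pass
    c0 <- z[rep(1L, nrow(z)), , drop = FALSE]
    iir_filter_mat(b, a, z - c0) + g * c0
  }
  y <- pass(rbind(pre, x, post))
  y <- pass(y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[pad + seq_len(n), , drop = FALSE]
}

#' Segment a continuous series into trial-locked blocks
#'
#' One block per experimental trial, spanning the 4 s of the preceding
#' reference trial, the experimental trial, plus the following reference
#' trial (extended to at least `post_min_s` after onset so every block
#' covers the full analysis range). Blocks truncated by the edges of the
#' recording, or lacking a following reference trial, are flagged
#' `incomplete` rather than dropped.
#'
#' @param x Numeric matrix (series x time) or vector.
#' @param schedule Schedule aligned to the series (sample 1 = time 0).
#' @param fs Sampling rate in Hz.
#' @param pre_s Pre-onset baseline span (default 4 s).
#' @param post_min_s Minimum post-onset coverage (default 20 s).
#' @return List of blocks; each is a list with `trial_id`, `condition`,
#'   `onset_s`, `rel_time` (seconds from trial onset), `data`
#'   (series x time), and `incomplete`.
#' @export
segment_blocks <- function(x, schedule, fs, pre_s = 4, post_min_s = 20) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n_t <- ncol(x)
  exp_tr <- experimental_trials(schedule)
  blocks <- vector("list", nrow(exp_tr))
  for (i in seq_len(nrow(exp_tr))) {
    tr <- exp_tr[i, ]
    row <- which(schedule$trial_id == tr$trial_id)
    has_ref <- row < nrow(schedule) && schedule$condition[row + 1L] == "REF"
    ref_end <- if (has_ref) {
      schedule$onset_s[row + 1L] + schedule$duration_s[row + 1L]
    } else {
      tr$onset_s + tr$duration_s
    }
    onset_idx <- round(tr$onset_s * fs) + 1L
    start_idx <- onset_idx - round(pre_s * fs)
    end_idx <- max(onset_idx + round(post_min_s * fs),
                   round(ref_end * fs) + 1L)
    incomplete <- !has_ref || start_idx < 1L || end_idx > n_t
    idx <- max(1L, start_idx):min(n_t, end_idx)
    blocks[[i]] <- list(
      trial_id = tr$trial_id, condition = tr$condition,
      onset_s = tr$onset_s,
      rel_time = (idx - onset_idx) / fs,
      data = x[, idx, drop = FALSE],
      incomplete = incomplete
    )
  }
  blocks
}

#' Linearly detrend a block
#'
#' Subtracts the line through the two anchor points (centre of the first
#' `anchor_s` seconds, mean over that span) and (centre of the last
#' `anchor_s` seconds, mean over that span). After detrending the means of
#' the first and last spans are equal (and zero-mean differences removed);
#' any exactly linear trend is removed completely.
#'
#' @param data Numeric matrix (series x time) or vector.
#' @param rel_time Time axis of the block in seconds.
#' @param anchor_s Anchor span in seconds (default 4).
#' @return Detrended data, same shape as `data`.
#' @export
detrend_block <- function(data, rel_time, anchor_s = 4) {
  vec <- !is.matrix(data)
  if (vec) data <- matrix(data, nrow = 1)
  span <- rel_time[length(rel_time)] - rel_time[1]
  if (span < 2 * anchor_s - 1e-9) {
    stop("block must be at least ", 2 * anchor_s, " s long", call. = FALSE)
  }
  i1 <- which(rel_time < rel_time[1] + anchor_s - 1e-9)
  i2 <- which(rel_time > rel_time[length(rel_time)] - anchor_s + 1e-9)
  c1 <- mean(rel_time[i1]); c2 <- mean(rel_time[i2])
  m1 <- rowMeans(data[, i1, drop = FALSE])
  m2 <- rowMeans(data[, i2, drop = FALSE])
  slope <- (m2 - m1) / (c2 - c1)
  fit <- outer(slope, rel_time - c1) + m1
  out <- data - fit
  if (vec) out[1, ] else out
}

#' Preprocess a recording into concentration blocks
#'
#' The full chain from raw intensity to trial-locked chromophore
#' concentration changes: attenuation conversion, zero-phase 1.7 Hz low-pass
#' on the continuous series, segmentation into trial blocks, linear
#' detrending of each block, and inversion of the modified Beer-Lambert law.
#' Stages can be toggled for diagnostic use; the defaults run the complete
#' chain.
#'
#' @param recording A [nirs_recording].
#' @param schedule The stimulus schedule of the recording.
#' @param mbll [mbll_parameters()].
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param lowpass_filter,detrend Logical stage toggles.
#' @param pre_s,post_min_s Block span parameters (see [segment_blocks()]).
#' @return Object of class `concentration_blocks`: list with `blocks` (each
#'   with `trial_id`, `condition`, `rel_time`, `hbo` and `hhb` matrices
#'   `channels x time` in micromolar, `incomplete`), `channels`, and
#'   `sampling_rate_hz`.
#' @export
preprocess_recording <- function(recording, schedule,
                                 mbll = mbll_parameters(),
                                 cutoff_hz = 1.7,
                                 lowpass_filter = TRUE, detrend = TRUE,
                                 pre_s = 4, post_min_s = 20) {
  fs <- recording$sampling_rate_hz
  att <- intensity_to_attenuation(recording)
  a770 <- att[, 1, , drop = TRUE]
  a850 <- att[, 2, , drop = TRUE]
  if (is.null(dim(a770))) {
    a770 <- matrix(a770, nrow = 1)
    a850 <- matrix(a850, nrow = 1)
  }
  if (lowpass_filter) {
    both <- lowpass(rbind(a770, a850), fs, cutoff_hz)
    a770 <- both[seq_len(nrow(a770)), , drop = FALSE]
    a850 <- both[nrow(a770) + seq_len(nrow(a850)), , drop = FALSE]
  }
  b770 <- segment_blocks(a770, schedule, fs, pre_s, post_min_s)
  b850 <- segment_blocks(a850, schedule, fs, pre_s, post_min_s)
  blocks <- vector("list", length(b770))
  for (i in seq_along(b770)) {
    d770 <- b770[[i]]$data
    d850 <- b850[[i]]$data
    if (detrend && !b770[[i]]$incomplete) {
      d770 <- detrend_block(d770, b770[[i]]$rel_time)
      d850 <- detrend_block(d850, b850[[i]]$rel_time)
    }
    conc <- mbll_convert(d770, d850, mbll)
    blocks[[i]] <- list(trial_id = b770[[i]]$trial_id,
                        condition = b770[[i]]$condition,
                        rel_time = b770[[i]]$rel_time,
                        hbo = conc$hbo, hhb = conc$hhb,
                        incomplete = b770[[i]]$incomplete)
  }
  structure(list(blocks = blocks, channels = recording$channels,
                 sampling_rate_hz = fs),
            class = "concentration_blocks")
}
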