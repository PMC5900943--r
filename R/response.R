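#' Average valid trials within channels
#'
#' For each channel and experimental condition, averages the trial-locked
#' concentration blocks of the trials marked valid in the finalized ledger,
#' on the common `[-pre_s, post_s]` grid. Channel-condition cells with fewer
#' than `min_trials` valid complete trials are absent (`NA`), not
#' zero-filled.
#'
#' @param blocks A [preprocess_recording()] result.
#' @param ledger Validity ledger from [build_validity_ledger()] (or the
#'   `ledger` element of [apply_inclusion_rules()]).
#' @param min_trials Minimum valid trials per condition.
#' @param pre_s,post_s Averaging span in seconds relative to trial onset.
#' @return Object of class `channel_average`: list with `rel_time`, arrays
#'   `hbo` and `hhb` (`channels x conditions x time`), `n_trials`
#'   (`channels x conditions`), and `channels`.
#' @export
average_trials <- function(blocks, ledger, min_trials = 3, pre_s = 4,
                           post_s = 20) {
  fs <- blocks$sampling_rate_hz
  n_keep <- round(pre_s * fs) + round(post_s * fs) + 1L
  rel_time <- (seq_len(n_keep) - 1L - round(pre_s * fs)) / fs
  probe <- blocks$channels
  conds <- experimental_conditions()
  n_ch <- nrow(probe)
  hbo <- array(NA_real_, c(n_ch, length(conds), n_keep),
               dimnames = list(NULL, conds, NULL))
  hhb <- hbo
  n_trials <- matrix(0L, n_ch, length(conds), dimnames = list(NULL, conds))

  # validity lookup matrix: channels x trials
  all_trials <- vapply(blocks$blocks, function(b) b$trial_id, integer(1))
  vm <- matrix(FALSE, n_ch, length(all_trials))
  li <- cbind(match(ledger$channel_id, probe$channel_id),
              match(ledger$trial_id, all_trials))
  ok <- !is.na(li[, 1]) & !is.na(li[, 2])
  vm[li[ok, , drop = FALSE]] <- ledger$valid[ok]
  for (j in seq_along(conds)) {
    sel <- which(vapply(blocks$blocks, function(b) {
      b$condition == conds[j] && !b$incomplete
    }, logical(1)))
    if (length(sel) == 0L) next
    hbo_stack <- vapply(blocks$blocks[sel],
                        function(b) b$hbo[, seq_len(n_keep), drop = FALSE],
                        matrix(0, n_ch, n_keep))
    hhb_stack <- vapply(blocks$blocks[sel],
                        function(b) b$hhb[, seq_len(n_keep), drop = FALSE],
                        matrix(0, n_ch, n_keep))
    for (ch in seq_len(n_ch)) {
      use <- which(vm[ch, sel])
      if (length(use) < min_trials) next
      hbo[ch, j, ] <- rowMeans(hbo_stack[ch, , use, drop = FALSE], dims = 2)
      hhb[ch, j, ] <- rowMeans(hhb_stack[ch, , use, drop = FALSE], dims = 2)
      n_trials[ch, j] <- length(use)
    }
  }
  structure(list(rel_time = rel_time, hbo = hbo, hhb = hhb,
                 n_trials = n_trials, channels = probe),
            class = "channel_average")
}

# mean of x over rel_time in [a, b]; inclusive endpoints with tolerance
span_mean <- function(x, rel_time, a, b, tol = 1e-9) {
  idx <- rel_time >= a - tol & rel_time <= b + tol
  if (!any(idx)) stop("time course does not cover [", a, ", ", b, "] s",
                      call. = FALSE)
  mean(x[idx])
}

#' Windowed peak change of an averaged time course
#'
#' The maximum signal change within the window relative to the pre-stimulus
#' baseline: for oxy-haemoglobin the signed extremum is the maximum, for
#' deoxy-haemoglobin the minimum (activation is an HbO2 increase or an HHb
#' decrease). The baseline is the mean over the 4 s immediately preceding
#' stimulus onset (`[-4, 0)`).
#'
#' @param x Averaged time course (vector).
#' @param rel_time Trial-locked time axis in seconds.
#' @param window Length-2 window in seconds (endpoints included).
#' @param chromophore `"HbO2"` or `"HHb"`.
#' @param baseline Length-2 baseline span; right endpoint excluded.
#' @return Peak change minus baseline mean (micromolar).
#' @export
window_peak <- function(x, rel_time, window = c(8, 12),
                        chromophore = c("HbO2", "HHb"),
                        baseline = c(-4, 0)) {
  chromophore <- match.arg(chromophore)
  tol <- 1e-9
  bidx <- rel_time >= baseline[1] - tol & rel_time < baseline[2] - tol
  widx <- rel_time >= window[1] - tol & rel_time <= window[2] + tol
  if (!any(bidx) || !any(widx)) {
    stop("time course does not cover the baseline and window spans",
         call. = FALSE)
  }
  extremum <- if (chromophore == "HbO2") max(x[widx]) else min(x[widx])
  extremum - mean(x[bidx])
}

#' All windowed peaks of a channel average
#'
#' @param avg A [average_trials()] result.
#' @param windows List of analysis windows (default 8--12 and 12--16 s).
#' @return `data.frame` with `channel_id`, `condition`, `chromophore`,
#'   `window`, `n_trials`, `peak`; absent channel-condition cells are
#'   omitted.
#' @export
window_peaks <- function(avg, windows = list(c(8, 12), c(12, 16))) {
  conds <- colnames(avg$n_trials)
  tol <- 1e-9
  rel <- avg$rel_time
  bidx <- rel >= -4 - tol & rel < 0 - tol
  cells <- which(avg$n_trials > 0L, arr.ind = TRUE)
  if (nrow(cells) == 0L) {
    return(data.frame(channel_id = integer(0), condition = character(0),
                      chromophore = character(0), window = character(0),
                      n_trials = integer(0), peak = numeric(0)))
  }
  out <- vector("list", length(windows) * 2L)
  k <- 0L
  for (w in windows) {
    widx <- rel >= w[1] - tol & rel <= w[2] + tol
    for (chromo in c("HbO2", "HHb")) {
      x <- if (chromo == "HbO2") avg$hbo else avg$hhb
      base <- rowMeans(x[, , bidx, drop = FALSE], dims = 2)
      ext <- apply(x[, , widx, drop = FALSE], c(1, 2),
                   if (chromo == "HbO2") max else min)
      k <- k + 1L
      out[[k]] <- quick_df(
        channel_id = avg$channels$channel_id[cells[, 1]],
        condition = conds[cells[, 2]],
        chromophore = rep(chromo, nrow(cells)),
        window = rep(paste0(w[1], "-", w[2]), nrow(cells)),
        n_trials = avg$n_trials[cells],
        peak = (ext - base)[cells])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(channel_id = integer(0), condition = character(0),
                      chromophore = character(0), window = character(0),
                      n_trials = integer(0), peak = numeric(0)))
  }
  rownames(res) <- NULL
  res
}

#' Epoch labels of the 0--20 s summary
#' @return Character vector `"0-4"` ... `"16-20"`.
#' @export
epoch_labels <- function() c("0-4", "4-8", "8-12", "12-16", "16-20")

#' Down-sample a time course into baseline-corrected 4-s epochs
#'
#' Averages the time course within each 4-s epoch between 0 and 20 s
#' post-onset and subtracts one scalar -- the mean response between t = 0
#' and t = 0.1 s -- from every epoch, anchoring the response at stimulus
#' onset. Adding any constant to the input leaves the output unchanged.
#'
#' @param x Time course (vector).
#' @param rel_time Trial-locked time axis in seconds; must cover
#'   `[0, 20]` s.
#' @param baseline_span Onset anchor span (default `c(0, 0.1)`).
#' @return Named vector of five baseline-corrected epoch means.
#' @export
epoch_summarize <- function(x, rel_time, baseline_span = c(0, 0.1)) {
  correction <- span_mean(x, rel_time, baseline_span[1], baseline_span[2])
  edges <- seq(0, 20, by = 4)
  vals <- vapply(seq_len(5), function(k) {
    span_mean(x, rel_time, edges[k], edges[k + 1])
  }, numeric(1)) - correction
  names(vals) <- epoch_labels()
  vals
}

#' Epoch summaries for every channel-condition cell
#'
#' @param avg A [average_trials()] result.
#' @param chromophores Chromophores to summarize.
#' @return Long `data.frame` with `channel_id`, `condition`, `chromophore`,
#'   `epoch`, `value`.
#' @export
epoch_summaries <- function(avg, chromophores = c("HbO2", "HHb")) {
  conds <- colnames(avg$n_trials)
  tol <- 1e-9
  rel <- avg$rel_time
  cells <- which(avg$n_trials > 0L, arr.ind = TRUE)
  if (nrow(cells) == 0L) {
    return(data.frame(channel_id = integer(0), condition = character(0),
                      chromophore = character(0), epoch = character(0),
                      value = numeric(0)))
  }
  edges <- seq(0, 20, by = 4)
  cidx <- rel >= -tol & rel <= 0.1 + tol
  out <- vector("list", length(chromophores) * 5L)
  k <- 0L
  for (chromo in chromophores) {
    x <- if (chromo == "HbO2") avg$hbo else avg$hhb
    corr <- rowMeans(x[, , cidx, drop = FALSE], dims = 2)
    for (e in seq_len(5)) {
      eidx <- rel >= edges[e] - tol & rel <= edges[e + 1] + tol
      vals <- rowMeans(x[, , eidx, drop = FALSE], dims = 2) - corr
      k <- k + 1L
      out[[k]] <- quick_df(
        channel_id = avg$channels$channel_id[cells[, 1]],
        condition = conds[cells[, 2]],
        chromophore = rep(chromo, nrow(cells)),
        epoch = rep(epoch_labels()[e], nrow(cells)),
        value = vals[cells])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROI-average epoch responses
#'
#' Averages epoch summaries across an infant's retained channels within each
#' ROI and hemisphere. ROI cells with no valid channel are absent.
#'
#' @param epochs Result of [epoch_summaries()].
#' @param probe Probe map.
#' @param channel_inclusion `data.frame` with `channel_id`, `included` (the
#'   `channels` element of [apply_inclusion_rules()]); if `NULL`, all
#'   channels present in `epochs` are used.
#' @return `data.frame` with `roi`, `hemisphere`, `condition`,
#'   `chromophore`, `epoch`, `value`, `n_channels`.
#' @export
roi_average <- function(epochs, probe, channel_inclusion = NULL) {
  if (!is.null(channel_inclusion)) {
    keep <- channel_inclusion$channel_id[channel_inclusion$included]
    epochs <- epochs[epochs$channel_id %in% keep, , drop = FALSE]
  }
  epochs$roi <- probe$roi[match(epochs$channel_id, probe$channel_id)]
  epochs$hemisphere <- probe$hemisphere[match(epochs$channel_id,
                                              probe$channel_id)]
  epochs <- epochs[epochs$roi != "none" & !is.na(epochs$value), ,
                   drop = FALSE]
  if (nrow(epochs) == 0L) {
    return(data.frame(roi = character(0), hemisphere = character(0),
                      condition = character(0), chromophore = character(0),
                      epoch = character(0), value = numeric(0),
                      n_channels = integer(0)))
  }
  key <- paste(epochs$roi, epochs$hemisphere, epochs$condition,
               epochs$chromophore, epochs$epoch, sep = "\r")
  sums <- rowsum(epochs$value, key)
  cnts <- rowsum(rep(1L, nrow(epochs)), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  quick_df(
    roi = vapply(parts, `[`, "", 1L),
    hemisphere = vapply(parts, `[`, "", 2L),
    condition = vapply(parts, `[`, "", 3L),
    chromophore = vapply(parts, `[`, "", 4L),
    epoch = vapply(parts, `[`, "", 5L),
    value = as.vector(sums) / as.vector(cnts),
    n_channels = as.integer(cnts))
}

#' Vocal minus non-vocal difference scores
#'
#' Per ROI, hemisphere and analysis epoch (8--12 and 12--16 s), the
#' difference between the responses to the auditory vocal and non-vocal
#' conditions. Cells where either condition is missing are absent.
#'
#' @param roi_responses Result of [roi_average()] (any chromophores).
#' @param epochs Epochs to difference (default the two analysis windows).
#' @return `data.frame` with `roi`, `hemisphere`, `chromophore`, `epoch`,
#'   `difference`.
#' @export
vocal_contrast <- function(roi_responses, epochs = c("8-12", "12-16")) {
  av <- roi_responses[roi_responses$condition == "A-V" &
                        roi_responses$epoch %in% epochs, , drop = FALSE]
  anv <- roi_responses[roi_responses$condition == "A-NV" &
                         roi_responses$epoch %in% epochs, , drop = FALSE]
  key <- function(d) paste(d$roi, d$hemisphere, d$chromophore, d$epoch)
  m <- match(key(av), key(anv))
  ok <- !is.na(m)
  data.frame(roi = av$roi[ok], hemisphere = av$hemisphere[ok],
             chromophore = av$chromophore[ok], epoch = av$epoch[ok],
             difference = av$value[ok] - anv$value[m[ok]],
             stringsAsFactors = FALSE)
}

#' Channel-wise group tests with FDR correction
#'
#' Two-tailed t-tests of the windowed peak changes across infants, per
#' channel: for the visual contrast, a one-sample test of the
#' baseline-referenced `V-S` peaks against zero; for the auditory contrast,
#' a paired test of `A-V` versus `A-NV` peaks within infants.
#' Benjamini-Hochberg adjustment is applied across channels within each
#' chromophore-by-window family. Channels contributed by fewer than two
#' infants are dropped. Zero-variance samples use the documented
#' conventions: all-zero differences give `t = 0`, `p = 1`; a non-zero
#' constant effect gives `p = 0`.
#'
#' @param peaks Stacked [window_peaks()] tables across infants, with an
#'   `infant_id` column.
#' @param contrast `"visual"` or `"auditory"`.
#' @return `data.frame` with `channel_id`, `chromophore`, `window`, `n`,
#'   `estimate`, `t`, `df`, `p`, `p_fdr`; attribute `"dropped"` lists
#'   channel cells with insufficient infants.
#' @export
channelwise_tests <- function(peaks, contrast = c("visual", "auditory")) {
  contrast <- match.arg(contrast)
  if (contrast == "visual") {
    dat <- peaks[peaks$condition == "V-S", , drop = FALSE]
    dat$value <- dat$peak
  } else {
    av <- peaks[peaks$condition == "A-V", , drop = FALSE]
    anv <- peaks[peaks$condition == "A-NV", , drop = FALSE]
    key <- function(d) paste(d$infant_id, d$channel_id, d$chromophore,
                             d$window)
    m <- match(key(av), key(anv))
    ok <- !is.na(m)
    dat <- av[ok, , drop = FALSE]
    dat$value <- av$peak[ok] - anv$peak[m[ok]]
  }
  cells <- unique(dat[, c("channel_id", "chromophore", "window")])
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- dat$channel_id == cells$channel_id[i] &
      dat$chromophore == cells$chromophore[i] &
      dat$window == cells$window[i]
    v <- dat$value[sel]
    if (length(v) < 2L) {
      dropped[[length(dropped) + 1L]] <- cells[i, ]
      next
    }
    m0 <- mean(v)
    s <- stats::sd(v)
    if (s < .Machine$double.eps) {
      tval <- if (abs(m0) < .Machine$double.eps) 0 else Inf * sign(m0)
      pval <- if (abs(m0) < .Machine$double.eps) 1 else 0
    } else {
      tval <- m0 / (s / sqrt(length(v)))
      pval <- 2 * stats::pt(-abs(tval), df = length(v) - 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      channel_id = cells$channel_id[i], chromophore = cells$chromophore[i],
      window = cells$window[i], n = length(v), estimate = m0, t = tval,
      df = length(v) - 1L, p = pval)
  }
  if (length(rows) == 0L) {
    res <- data.frame(channel_id = integer(0), chromophore = character(0),
                      window = character(0), n = integer(0),
                      estimate = numeric(0), t = numeric(0), df = numeric(0),
                      p = numeric(0), p_fdr = numeric(0))
  } else {
    res <- do.call(rbind, rows)
    res$p_fdr <- NA_real_
    for (fam in split(seq_len(nrow(res)),
                      paste(res$chromophore, res$window))) {
      res$p_fdr[fam] <- stats::p.adjust(res$p[fam], method = "BH")
    }
  }
  attr(res, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  res
}
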