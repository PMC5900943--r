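# Shared fixture builders. Everything is generated in code at test time.

# Deterministic, noise-free, artifact-free configuration on the reduced
# six-channel montage: the signal that goes in is exactly the signal the
# pipeline should read out.
quiet_config <- function(...) {
  args <- list(probe = small_probe_map(),
               noise = noise_spec(enable = FALSE),
               artifacts = artifact_spec(enable = FALSE),
               amplitude_sd = c(social = 0, vocal = 0),
               looking = looking_spec(fixed = 1))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# Minimal concentration_blocks container around explicit per-trial matrices.
make_blocks <- function(hbo_list, conditions, fs = 10, pre_s = 4,
                        probe = small_probe_map()[seq_len(nrow(hbo_list[[1]])), ],
                        hhb_list = NULL) {
  blocks <- lapply(seq_along(hbo_list), function(i) {
    n <- ncol(hbo_list[[i]])
    list(trial_id = 2L * i, condition = conditions[i],
         rel_time = (seq_len(n) - 1L - round(pre_s * fs)) / fs,
         hbo = hbo_list[[i]],
         hhb = if (is.null(hhb_list)) -hbo_list[[i]] / 3 else hhb_list[[i]],
         incomplete = FALSE)
  })
  structure(list(blocks = blocks, channels = probe, sampling_rate_hz = fs),
            class = "concentration_blocks")
}

# Ledger with every trial valid for the given blocks.
all_valid_ledger <- function(blocks) {
  looking <- data.frame(
    trial_id = vapply(blocks$blocks, function(b) b$trial_id, integer(1)),
    looking = 1)
  lk <- looking_validity(looking)
  intens <- data.frame(channel_id = blocks$channels$channel_id,
                       intensity_artifact = FALSE)
  conc <- data.frame(
    channel_id = rep(blocks$channels$channel_id,
                     times = length(blocks$blocks)),
    trial_id = rep(looking$trial_id, each = nrow(blocks$channels)),
    concentration_artifact = FALSE)
  build_validity_ledger(blocks, lk, intens, conc)
}

# Exhaustive Benjamini-Hochberg step-up oracle: the rejection set at level q
# found by checking every candidate cutoff k directly.
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  rejected <- logical(m)
  if (kmax > 0) rejected[ord[seq_len(kmax)]] <- TRUE
  rejected
}
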