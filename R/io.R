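#' Write a recording in the plain-TSV dialect
#'
#' Long format, one row per sample: columns `time_s`, `channel_id`,
#' `wavelength_nm`, `intensity`. The channel geometry travels in a sidecar
#' probe map (see [write_probe_map()]); `read_recording()` accepts the probe
#' map explicitly or looks for `<path>.probe.json`.
#'
#' @param recording A [nirs_recording].
#' @param path Output TSV path.
#' @param probe_path Optional sidecar path for the probe map (default
#'   `<path>.probe.json`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            probe_path = paste0(path, ".probe.json")) {
  dims <- dim(recording$intensity)
  tt <- (seq_len(dims[3]) - 1L) / recording$sampling_rate_hz
  long <- data.frame(
    time_s = sprintf("%.10g", rep(tt, each = dims[1] * 2L)),
    channel_id = rep(recording$channels$channel_id, times = 2L * dims[3]),
    wavelength_nm = rep(rep(recording$wavelengths_nm, each = dims[1]),
                        times = dims[3]),
    intensity = sprintf("%.17g", as.vector(recording$intensity))
  )
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_probe_map(recording$channels, probe_path)
  invisible(path)
}

#' Read a recording
#'
#' Reads the documented plain-TSV dialect back into a [nirs_recording],
#' validating the container invariants: strictly positive intensity, both
#' wavelengths present for every channel, and uniform sampling. Violations
#' are rejected with a diagnostic naming the offending channel and sample.
#'
#' @param path Path to the TSV file.
#' @param dialect `"tsv"` (the HDF5-based container dialect is not provided
#'   by this package).
#' @param probe Probe map `data.frame`; if `NULL`, read from
#'   `<path>.probe.json`.
#' @return A [nirs_recording].
#' @export
read_recording <- function(path, dialect = c("tsv", "snirf"), probe = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "snirf") {
    stop("the HDF5-based container dialect is not supported by this ",
         "package; write and read the TSV dialect instead", call. = FALSE)
  }
  long <- utils::read.delim(path, sep = "\t")
  req <- c("time_s", "channel_id", "wavelength_nm", "intensity")
  if (!all(req %in% names(long))) {
    stop("recording TSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(probe)) probe <- read_probe_map(paste0(path, ".probe.json"))
  ch_ids <- probe$channel_id
  times <- sort(unique(long$time_s))
  if (length(times) > 2L) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      stop("non-uniform sampling in recording", call. = FALSE)
    }
  }
  fs <- 1 / stats::median(diff(times))
  wls <- sort(unique(long$wavelength_nm))
  if (!identical(as.numeric(wls), c(770, 850))) {
    stop("recording must contain wavelengths 770 and 850 nm; found: ",
         paste(wls, collapse = ", "), call. = FALSE)
  }
  bad <- which(long$intensity <= 0 | !is.finite(long$intensity))
  if (length(bad) > 0L) {
    b <- bad[1]
    stop(sprintf(
      "non-positive intensity at channel %d, wavelength %g nm, time %.3f s",
      long$channel_id[b], long$wavelength_nm[b], long$time_s[b]),
      call. = FALSE)
  }
  n_t <- length(times)
  intensity <- array(NA_real_, c(length(ch_ids), 2L, n_t))
  t_idx <- match(long$time_s, times)
  c_idx <- match(long$channel_id, ch_ids)
  w_idx <- match(long$wavelength_nm, c(770, 850))
  if (anyNA(c_idx)) {
    stop("recording contains channel ids absent from the probe map",
         call. = FALSE)
  }
  intensity[cbind(c_idx, w_idx, t_idx)] <- long$intensity
  if (anyNA(intensity)) {
    miss <- which(is.na(intensity), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "missing sample for channel %d, wavelength %s nm",
      ch_ids[miss[1]], c("770", "850")[miss[2]]), call. = FALSE)
  }
  nirs_recording(intensity, probe, fs, meta = list(source = path))
}

#' Read and write stimulus schedules, looking codes and phenotypes
#'
#' Schedules and looking codes are TSV; phenotypes are CSV; ground truth is
#' JSON. All writers produce files their paired readers accept.
#'
#' @param schedule,looking,phenotypes Objects to write.
#' @param path File path.
#' @return The read object, or `path` invisibly for writers.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_schedule <- function(path) {
  sched <- utils::read.delim(path, sep = "\t")
  class(sched) <- c("nirs_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

#' @rdname io_tables
#' @export
write_looking <- function(looking, path) {
  utils::write.table(looking, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_looking <- function(path) utils::read.delim(path, sep = "\t")

#' @rdname io_tables
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read simulation ground truth
#'
#' @param truth Ground-truth list from [simulate_infant()].
#' @param path JSON path.
#' @return The truth list (reader), or `path` invisibly (writer).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write result tables and a run manifest
#'
#' Emits each table as TSV with documented headers (an empty table produces
#' a headers-only file) and a JSON manifest with the seed, configuration
#' hash, package version and per-stage counts, sufficient to re-run the
#' pipeline bit-identically.
#'
#' @param tables Named list of `data.frame`s (e.g. `channel_stats`,
#'   `roi_responses`, `validity_ledger`, `model_terms`, `correlations`).
#' @param out_dir Output directory (created if absent).
#' @param manifest Named list of manifest fields (`seed`, `config_hash`,
#'   `counts`, ...).
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(tables, out_dir, manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  manifest$package_version <- as.character(utils::packageVersion("nirsocial"))
  manifest$written <- format(Sys.time(), tz = "UTC")
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}

# Stable hash of an R object (used for the manifest's config hash).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
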