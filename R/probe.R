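#' Region-of-interest labels
#'
#' The three social-brain regions of interest covered by the probe arrays:
#' inferior frontal gyrus (IFG), anterior middle/superior temporal gyri
#' (aMTG-STG) and posterior superior temporal sulcus / temporoparietal
#' junction (pSTS-TPJ); `"none"` marks channels outside every ROI.
#'
#' @return Character vector of valid ROI labels.
#' @export
roi_labels <- function() c("IFG", "aMTG-STG", "pSTS-TPJ", "none")

#' Default 26-channel probe layout
#'
#' A synthetic stand-in for the anatomically co-registered channel-to-ROI
#' map of a two-array temporal-frontal montage: 13 channels per hemisphere
#' at 2 cm source-detector separation, with frontal channels assigned to
#' IFG, anterior temporal channels to aMTG-STG, posterior temporal channels
#' to pSTS-TPJ, and one unassigned channel per hemisphere. The true
#' channel-to-anatomy assignment of any real montage should be supplied as
#' configuration via [read_probe_map()].
#'
#' @return A `data.frame` with columns `channel_id` (1..26), `hemisphere`
#'   (`"left"`/`"right"`), `separation_cm` (2.0), `roi`.
#' @export
default_probe_map <- function() {
  per_hemi <- c(rep("IFG", 4), rep("aMTG-STG", 4), rep("pSTS-TPJ", 4), "none")
  data.frame(
    channel_id = 1:26,
    hemisphere = rep(c("left", "right"), each = 13),
    separation_cm = 2.0,
    roi = rep(per_hemi, 2),
    stringsAsFactors = FALSE
  )
}

#' Reduced six-channel probe layout
#'
#' One channel per ROI and hemisphere at 2 cm separation. Intended for
#' simulation studies where the full 26-channel montage adds computation
#' without changing the ROI-level statistics being studied.
#'
#' @return A probe map `data.frame` as in [default_probe_map()].
#' @export
small_probe_map <- function() {
  data.frame(
    channel_id = 1:6,
    hemisphere = rep(c("left", "right"), each = 3),
    separation_cm = 2.0,
    roi = rep(c("IFG", "aMTG-STG", "pSTS-TPJ"), 2),
    stringsAsFactors = FALSE
  )
}

#' Validate a probe map
#'
#' @param probe A probe map `data.frame`.
#' @return The probe map, invisibly; errors with a diagnostic on violation.
#' @export
validate_probe_map <- function(probe) {
  req <- c("channel_id", "hemisphere", "separation_cm", "roi")
  missing <- setdiff(req, names(probe))
  if (length(missing) > 0L) {
    stop("probe map is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(probe$channel_id)) {
    stop("duplicated channel_id in probe map: ",
         paste(unique(probe$channel_id[duplicated(probe$channel_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(probe$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  bad <- setdiff(unique(probe$roi), roi_labels())
  if (length(bad) > 0L) {
    stop("unknown ROI label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(probe$separation_cm)) || any(probe$separation_cm <= 0)) {
    stop("source-detector separations must be positive", call. = FALSE)
  }
  rois <- setdiff(unique(probe$roi), "none")
  for (r in rois) {
    hemis <- unique(probe$hemisphere[probe$roi == r])
    if (!all(c("left", "right") %in% hemis)) {
      stop("ROI '", r, "' must appear in both hemispheres", call. = FALSE)
    }
  }
  invisible(probe)
}

#' Read a probe map from JSON
#'
#' The file must contain an array of objects with fields `channel_id`,
#' `hemisphere`, `separation_cm` and `roi`. ROI membership is consumed as
#' configuration; anatomical co-registration is out of scope.
#'
#' @param path Path to a JSON probe map.
#' @return A validated probe map `data.frame`.
#' @export
read_probe_map <- function(path) {
  probe <- jsonlite::fromJSON(path)
  if (!is.data.frame(probe)) stop("probe map JSON must be an array of objects",
                                  call. = FALSE)
  validate_probe_map(probe)
  probe[order(probe$channel_id), , drop = FALSE]
}

#' Write a probe map to JSON
#'
#' @param probe A probe map `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(probe, path) {
  validate_probe_map(probe)
  jsonlite::write_json(probe, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
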