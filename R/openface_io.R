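#' Quality-control configuration for frame-level tracking data
#'
#' @param min_confidence Minimum tracking confidence (0-1) a frame must reach
#'   to be retained. The tracker reports a unitless reliability score per
#'   frame; 0.75 is a conventional cut for usable face tracking.
#' @param min_retained Minimum fraction of a trial's frames that must survive
#'   quality filtering for the trial to be kept; below it the trial is flagged
#'   excluded (mirroring behavioural exclusions such as covering the face or
#'   leaving the camera frame, applied per trial because the trial is the unit
#'   of analysis).
#' @param min_frames Minimum number of retained frames for a trial to be
#'   usable (default 300, about 10 s at 30 fps).
#' @return A list of class `qc_config`.
#' @export
#' @examples
#' qc_config(min_confidence = 0.8)
qc_config <- function(min_confidence = 0.75, min_retained = 0.5,
                      min_frames = 300L) {
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1,
            min_confidence >= 0, min_confidence <= 1,
            is.numeric(min_retained), min_retained >= 0, min_retained <= 1,
            is.numeric(min_frames), min_frames >= 1)
  structure(list(min_confidence = min_confidence,
                 min_retained = min_retained,
                 min_frames = as.integer(min_frames)),
            class = "qc_config")
}

#' Gaze-fixation configuration
#'
#' @param threshold Angular threshold in radians: a frame counts as
#'   gaze-on-screen when the gaze-angle magnitude
#'   `sqrt(gaze_angle_x^2 + gaze_angle_y^2)` is at or below it. Default
#'   0.1745 rad (10 degrees), a screen-sized cone at typical webcam viewing
#'   distance; the choice is recorded in output metadata.
#' @return A list of class `gaze_config`.
#' @export
gaze_config <- function(threshold = 0.1745) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  structure(list(threshold = threshold), class = "gaze_config")
}

# Mandatory non-AU columns of a tracking CSV
.of_required <- c("frame", "timestamp", "confidence", "success",
                  "gaze_angle_x", "gaze_angle_y")

#' Read a frame-level face-tracking CSV
#'
#' Reads an OpenFace-style tracking table: one row per video frame with a
#' frame index, timestamp, tracking confidence, success flag, gaze angles and
#' per-AU intensity regressions in columns named like `AU06_r` (0-5 scale).
#' Header names are stripped of surrounding whitespace (OpenFace emits
#' leading spaces); AU codes are normalised to `"AU"` plus two digits;
#' intensities are clamped into \[0, 5\] and confidence into \[0, 1\], since
#' regression outputs can overshoot their nominal scale.
#'
#' @param path Path to the CSV file.
#' @param aus Optional character vector of AU codes to keep (e.g.
#'   `c("AU06", "AU12")`); default all AU columns present.
#' @return A data frame of class `of_track` with columns `frame`,
#'   `timestamp`, `confidence`, `success` (logical), `gaze_angle_x`,
#'   `gaze_angle_y` and one column per AU; the retained AU codes are in
#'   `attr(x, "au_codes")`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("frame, timestamp, confidence, success, gaze_angle_x, gaze_angle_y, AU06_r",
#'              "0, 0.00, 0.98, 1, 0.01, -0.02, 1.4",
#'              "1, 0.03, 0.97, 1, 0.02, 0.00, 5.7"), f)
#' tr <- read_track(f)
#' tr$AU06  # 5.7 clamped to 5
read_track <- function(path, aus = NULL) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(raw) <- trimws(names(raw))
  if (nrow(raw) == 0) stop("empty tracking file (no frames): ", path)

  missing_cols <- setdiff(.of_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("tracking file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  au_raw <- grep("^AU[0-9]{1,2}_r$", names(raw), value = TRUE)
  if (length(au_raw) == 0) {
    stop("tracking file ", path, " has no AU intensity (AU??_r) column")
  }
  codes <- sprintf("AU%02d", as.integer(sub("^AU([0-9]{1,2})_r$", "\\1", au_raw)))
  if (!is.null(aus)) {
    keep <- codes %in% aus
    if (!any(keep)) stop("none of the requested AUs present in ", path)
    au_raw <- au_raw[keep]; codes <- codes[keep]
  }

  track <- raw[.of_required]
  track$frame <- as.integer(track$frame)
  track$success <- if (is.numeric(track$success)) track$success != 0 else
    as.logical(track$success)
  track$confidence <- clamp(as.numeric(track$confidence), 0, 1)
  if (any(diff(track$frame) <= 0)) {
    stop("frame index not strictly increasing in ", path)
  }
  if (any(track$timestamp < 0)) stop("negative timestamp in ", path)

  for (i in seq_along(au_raw)) {
    track[[codes[i]]] <- clamp(as.numeric(raw[[au_raw[i]]]), 0, 5)
  }
  structure(track, au_codes = codes, class = c("of_track", "data.frame"))
}

#' Quality-filter the frames of a track
#'
#' Retains frames with `success = TRUE` and confidence at or above
#' `config$min_confidence`. Idempotent: filtering an already-filtered track
#' changes nothing. The fraction retained (relative to the input) is stored
#' in `attr(x, "retained_fraction")`.
#'
#' @param track An `of_track` data frame from [read_track()].
#' @param config A [qc_config()].
#' @param verbose Log a line with frames read/retained?
#' @return The filtered `of_track` (possibly zero rows).
#' @export
filter_frames <- function(track, config = qc_config(), verbose = FALSE) {
  stopifnot(inherits(track, "of_track"), inherits(config, "qc_config"))
  keep <- track$success & track$confidence >= config$min_confidence
  keep[is.na(keep)] <- FALSE
  out <- track[keep, , drop = FALSE]
  frac <- if (nrow(track) == 0) 0 else nrow(out) / nrow(track)
  attr(out, "au_codes") <- attr(track, "au_codes")
  attr(out, "retained_fraction") <- frac
  class(out) <- c("of_track", "data.frame")
  if (verbose) {
    log_line("frames read %d, retained %d (%.3f)", nrow(track), nrow(out), frac)
  }
  out
}

#' Read a trial-annotation table
#'
#' Annotations are a TSV with one row per eyes-open trial: columns
#' `subject_id`, `gender` (`M`/`F`), `condition` (`blank`, `own_face`,
#' `other_face`), `trial_index` (1-3) and the half-open, 0-based
#' `start_frame`/`end_frame` span into the trial's tracking file.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame with an added `trial_id` column
#'   (`subject.condition.trial`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "gender", "condition", "trial_index",
                "start_frame", "end_frame")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  validate_annotations(ann)
}

#' @noRd
validate_annotations <- function(ann) {
  if (nrow(ann) == 0) stop("annotation table is empty")
  bad <- which(!ann$gender %in% c("M", "F"))
  if (length(bad)) stop("unknown gender label in annotation row ", bad[1])
  bad <- which(!ann$condition %in% c("blank", "own_face", "other_face"))
  if (length(bad)) stop("unknown condition label in annotation row ", bad[1])
  bad <- which(!ann$trial_index %in% 1:3)
  if (length(bad)) stop("trial_index outside 1..3 in annotation row ", bad[1])
  bad <- which(ann$end_frame <= ann$start_frame)
  if (length(bad)) stop("empty frame span in annotation row ", bad[1])
  ann$trial_index <- as.integer(ann$trial_index)
  ann$trial_id <- trial_id(ann$subject_id, ann$condition, ann$trial_index)
  if (anyDuplicated(ann$trial_id)) stop("duplicate trial annotations")
  ann
}
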