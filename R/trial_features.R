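#' Range of an AU intensity series
#'
#' The per-trial summary of facial dynamics is the range of the AU's
#' expression values (max minus min) over the trial: during ~2 minutes of
#' still sitting, means and standard deviations are dominated by many small
#' random fluctuations, while the range captures the few genuine excursions.
#'
#' @param intensities Non-empty numeric vector of AU intensities.
#' @return `max(intensities) - min(intensities)`.
#' @export
#' @examples
#' au_range(c(0.1, 0.5, 0.3))  # 0.4
au_range <- function(intensities) {
  if (length(intensities) == 0 || all(is.na(intensities))) {
    stop("insufficient data: empty intensity series")
  }
  r <- range(intensities, na.rm = TRUE)
  r[2] - r[1]
}

#' Proportion of frames with gaze fixed on the screen
#'
#' Participants are not required to look at the screen, so the fraction of
#' time they do is itself informative. A frame counts as on-screen when the
#' gaze-angle magnitude `sqrt(gaze_angle_x^2 + gaze_angle_y^2)` is at or
#' below the angular threshold.
#'
#' @param track An `of_track` data frame (typically already QC-filtered).
#' @param config A [gaze_config()].
#' @return Proportion in \[0, 1\].
#' @export
gaze_on_screen_prop <- function(track, config = gaze_config()) {
  stopifnot(inherits(config, "gaze_config"))
  if (nrow(track) == 0) stop("insufficient data: no frames for gaze proportion")
  mag <- sqrt(track$gaze_angle_x^2 + track$gaze_angle_y^2)
  mean(mag <= config$threshold)
}

#' Per-trial instrumental feature vector
#'
#' Reduces one QC-filtered eyes-open trial to its instrumental covariates:
#' the expression range of every configured AU and the gaze-on-screen
#' proportion. A trial with fewer than `qc$min_frames` retained frames is
#' flagged excluded (features set to `NA`), never silently dropped.
#'
#' @param track QC-filtered `of_track` frames for this trial (already
#'   restricted to the trial's frame span).
#' @param annotation One-row data frame (or list) with `subject_id`,
#'   `gender`, `condition`, `trial_index`.
#' @param qc A [qc_config()]; only `min_frames` is used here.
#' @param gaze A [gaze_config()].
#' @param aus AU codes to summarise; default the AUs present in the track.
#' @return One-row data frame: design labels, `gaze_on_screen_prop`, one
#'   `<AU>_range` column per AU, `n_frames_used`, `excluded`.
#' @export
extract_trial_features <- function(track, annotation, qc = qc_config(),
                                   gaze = gaze_config(), aus = NULL) {
  aus <- aus %||% attr(track, "au_codes")
  stopifnot(length(aus) > 0)
  missing_aus <- setdiff(aus, names(track))
  if (length(missing_aus) > 0) {
    stop("track lacks AU column(s): ", paste(missing_aus, collapse = ", "))
  }
  n <- nrow(track)
  excluded <- n < qc$min_frames
  vals <- if (excluded) {
    rep(NA_real_, length(aus) + 1)
  } else {
    c(gaze_on_screen_prop(track, gaze),
      vapply(aus, function(a) au_range(track[[a]]), numeric(1)))
  }
  out <- data.frame(
    subject_id = annotation$subject_id,
    gender = annotation$gender,
    condition = annotation$condition,
    trial_index = as.integer(annotation$trial_index),
    stringsAsFactors = FALSE
  )
  out$gaze_on_screen_prop <- vals[1]
  for (i in seq_along(aus)) out[[paste0(aus[i], "_range")]] <- vals[i + 1]
  out$n_frames_used <- n
  out$excluded <- excluded
  out$trial_id <- trial_id(annotation$subject_id, annotation$condition,
                           annotation$trial_index)
  out
}

#' Trial-feature table for a whole cohort
#'
#' Applies frame QC and [extract_trial_features()] to every annotated trial.
#' For each annotation the trial's frames are taken from its frame span,
#' quality-filtered, and the trial is flagged excluded when the retained
#' fraction falls below `qc$min_retained` or fewer than `qc$min_frames`
#' frames survive.
#'
#' @param tracks Either a directory containing one tracking CSV per trial
#'   (named as [track_filename()]) or a named list of `of_track` data frames
#'   keyed by `trial_id`.
#' @param annotations Annotation data frame from [read_annotations()] (or
#'   validated equivalent).
#' @param qc A [qc_config()].
#' @param gaze A [gaze_config()].
#' @param aus AU codes forming the instrumental set; default
#'   [default_au_set()].
#' @param verbose Log one line per track?
#' @return Data frame of class `trial_features`, one row per annotation, with
#'   a `retained_fraction` column added.
#' @export
cohort_features <- function(tracks, annotations, qc = qc_config(),
                            gaze = gaze_config(), aus = default_au_set(),
                            verbose = FALSE) {
  if (!("trial_id" %in% names(annotations))) {
    annotations <- validate_annotations(annotations)
  }
  rows <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    track <- fetch_track(tracks, ann, aus)
    span <- track[track$frame >= ann$start_frame &
                    track$frame < ann$end_frame, , drop = FALSE]
    class(span) <- class(track)
    attr(span, "au_codes") <- attr(track, "au_codes")
    kept <- filter_frames(span, qc, verbose = verbose)
    frac <- attr(kept, "retained_fraction")
    row <- extract_trial_features(kept, ann, qc = qc, gaze = gaze, aus = aus)
    if (frac < qc$min_retained && !row$excluded) {
      row$excluded <- TRUE
      row$gaze_on_screen_prop <- NA_real_
      row[paste0(aus, "_range")] <- NA_real_
    }
    row$retained_fraction <- frac
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trial_features", "data.frame")
  out
}

#' @noRd
fetch_track <- function(tracks, ann, aus) {
  id <- trial_id(ann$subject_id, ann$condition, ann$trial_index)
  if (is.character(tracks) && length(tracks) == 1) {
    path <- file.path(tracks, track_filename(ann$subject_id, ann$condition,
                                             ann$trial_index))
    read_track(path, aus = aus)
  } else if (is.list(tracks)) {
    tr <- tracks[[id]]
    if (is.null(tr)) stop("no track supplied for trial ", id)
    tr
  } else {
    stop("tracks must be a directory path or a named list of of_track objects")
  }
}

#' Write a trial-feature table as TSV
#'
#' @param features A `trial_features` data frame from [cohort_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write_tsv(features, path)
  invisible(path)
}
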