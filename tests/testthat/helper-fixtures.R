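# Shared fixtures and independent oracles, all built in code at test time.

# Minimal in-memory track with given AU intensity columns
make_track <- function(n = 10, aus = c("AU06"), confidence = 0.95,
                       success = TRUE, gaze_x = 0, gaze_y = 0,
                       intensities = NULL) {
  tr <- data.frame(
    frame = seq_len(n) - 1L,
    timestamp = (seq_len(n) - 1L) / 30,
    confidence = rep_len(confidence, n),
    success = rep_len(success, n),
    gaze_angle_x = rep_len(gaze_x, n),
    gaze_angle_y = rep_len(gaze_y, n)
  )
  for (au in aus) {
    tr[[au]] <- if (is.null(intensities)) runif(n, 0, 2) else
      rep_len(intensities, n)
  }
  structure(tr, au_codes = aus, class = c("of_track", "data.frame"))
}

# Write a track to an OpenFace-style CSV (AU columns renamed to AU??_r)
write_track_csv <- function(track, path, header_spaces = FALSE) {
  out <- as.data.frame(track)
  aus <- attr(track, "au_codes")
  names(out)[match(aus, names(out))] <- paste0(aus, "_r")
  if (header_spaces) names(out) <- paste0(" ", names(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# Annotation table for a tiny designed cohort
make_annotations <- function(subjects = c("S01", "S02"),
                             genders = c("M", "F"),
                             conditions = c("blank", "own_face", "other_face"),
                             trials = 1:3, n_frames = 100L) {
  ann <- expand.grid(trial_index = trials, condition = conditions,
                     subject_id = subjects,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann$gender <- genders[match(ann$subject_id, subjects)]
  ann$start_frame <- 0L
  ann$end_frame <- as.integer(n_frames)
  ann[, c("subject_id", "gender", "condition", "trial_index",
          "start_frame", "end_frame")]
}

# Independent oracle for the first paired-axis covariance: brute-force grid
# search over unit-vector pairs (1-degree steps) of cov(B1 u, B2 v).
# Supports blocks with 1-3 columns. Blocks must already be centered.
grid_max_cov <- function(x1, x2, step_deg = 1) {
  unit_grid <- function(p) {
    step <- step_deg * pi / 180
    if (p == 1) {
      matrix(c(1, -1), ncol = 1)
    } else if (p == 2) {
      th <- seq(0, 2 * pi, by = step)
      cbind(cos(th), sin(th))
    } else if (p == 3) {
      th <- seq(0, 2 * pi, by = step)       # azimuth
      ph <- seq(0, pi, by = step)           # polar
      g <- expand.grid(th = th, ph = ph)
      cbind(sin(g$ph) * cos(g$th), sin(g$ph) * sin(g$th), cos(g$ph))
    } else {
      stop("grid oracle supports at most 3 columns")
    }
  }
  m <- crossprod(x1, x2) / (nrow(x1) - 1)
  ug <- unit_grid(ncol(x1))
  vg <- unit_grid(ncol(x2))
  a <- ug %*% m                             # |ug| x p2
  best <- -Inf
  chunk <- 5000L
  for (lo in seq(1L, nrow(vg), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(vg))
    best <- max(best, max(a %*% t(vg[lo:hi, , drop = FALSE])))
  }
  best
}

# Fast small cohort for end-to-end tests: full 18-subject design but short
# trials so every trial clears the default min_frames floor quickly.
fast_full_cohort <- function(seed = 1, trial_seconds = 15, effects = effect_spec()) {
  generate_cohort(cohort_spec(trial_seconds = trial_seconds, seed = seed),
                  effects)
}

# Assemble aligned blocks from a generated cohort
cohort_blocks <- function(co, qc = qc_config(), aus = default_au_set()) {
  fe <- cohort_features(co$tracks, co$annotations, qc = qc, aus = aus)
  align_blocks(fe, encode_features(co$annotations), aus = aus)
}
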