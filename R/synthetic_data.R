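#' Cohort specification for the synthetic study
#'
#' Describes the simulated study design: by default 18 subjects (8 men, 10
#' women), each recorded in 3 stimulus conditions (blank screen, own face,
#' other face) with 3 eyes-open trials of 2 minutes per condition, tracked
#' at 30 frames per second.
#'
#' @param n_subjects,n_men,n_women Cohort composition; `n_men + n_women`
#'   must equal `n_subjects`.
#' @param conditions Stimulus conditions.
#' @param trials_per_condition Eyes-open trials per condition.
#' @param trial_seconds Trial duration in seconds.
#' @param fps Video frame rate (frames per second).
#' @param seed RNG seed; fixes the cohort byte-for-byte.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18L, n_men = 8L, n_women = 10L,
                        conditions = c("blank", "own_face", "other_face"),
                        trials_per_condition = 3L, trial_seconds = 120,
                        fps = 30, seed = 1L) {
  stopifnot(n_subjects >= 1, n_men >= 0, n_women >= 0,
            n_men + n_women == n_subjects,
            length(conditions) >= 1,
            trials_per_condition >= 1, trial_seconds > 0, fps > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_men = as.integer(n_men), n_women = as.integer(n_women),
                 conditions = conditions,
                 trials_per_condition = as.integer(trials_per_condition),
                 trial_seconds = trial_seconds, fps = fps,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Planted-effect specification for the synthetic cohort
#'
#' Frame-level AU series are simulated as a per-subject baseline plus AR(1)
#' tracking noise plus sparse smooth "expression events" (raised-cosine
#' bumps of 0.5-2 s). The per-trial range statistic is driven by excursions,
#' so all planted effects act on event amplitude, not on the baseline:
#'
#' * gender on the dimpler/buccinator (AU14) and risorius (AU20): a main
#'   amplitude shift (up for women, down for men) in every trial, sharpened
#'   by an extra first-trial shift in the same directions, and mirrored in
#'   the gaze dwell probability (up for men, down for women);
#' * stimulus type on the cheek raiser (AU06): up for own face, down for
#'   blank screen — and on the gaze on-screen dwell probability in the same
#'   directions;
#' * third trial on the brow lowerer / depressor glabellae (AU04), chin
#'   raiser (AU17) and lips part (AU25): amplitude up;
#' * a subject random amplitude effect (individual specificity).
#'
#' Magnitudes are package defaults calibrated so the first latent
#' structure's variance share lands around 40-60% of the total; directions
#' follow the narrative the model is meant to recover (own face: cheek
#' raiser and gaze proportion up; blank screen: both down).
#'
#' @param aus AU set to simulate; default [default_au_set()].
#' @param baseline Baseline intensity per AU (recycled), 0-5 scale.
#' @param noise_sd Innovation sd of the AR(1) frame noise.
#' @param ar_rho Lag-1 autocorrelation of the frame noise.
#' @param event_rate_per_min Expected expression events per minute per AU.
#' @param event_amp Mean event amplitude (intensity units).
#' @param event_amp_sd Per-event amplitude jitter sd.
#' @param event_dur_range Event duration range in seconds.
#' @param subject_amp_sd Sd of the per-subject, per-AU amplitude effect.
#' @param gender_delta Named `c(M=, F=)` main amplitude deltas applied to
#'   `gender_first_trial_aus` in every trial.
#' @param gender_first_trial_delta Named `c(M=, F=)` extra amplitude deltas
#'   applied to `gender_first_trial_aus` in first trials.
#' @param gender_first_trial_aus AUs carrying the gender and gender x
#'   first-trial effects.
#' @param stimulus_au AU carrying the stimulus-type effect.
#' @param stimulus_delta Named amplitude delta per condition for
#'   `stimulus_au`.
#' @param third_trial_delta Amplitude delta applied to `third_trial_aus` in
#'   third trials.
#' @param third_trial_aus AUs carrying the third-trial effect.
#' @param gaze_dwell Named on-screen dwell probability per condition.
#' @param gaze_gender_delta Named `c(M=, F=)` dwell-probability deltas in
#'   every trial.
#' @param gaze_first_trial_delta Named `c(M=, F=)` extra dwell-probability
#'   deltas in first trials.
#' @param gaze_sd_on Not a dwell parameter: spread (radians) of on-screen
#'   gaze-angle magnitudes below the threshold.
#' @param gaze_threshold Angular threshold (radians) separating on- from
#'   off-screen frames; matches [gaze_config()]'s default.
#' @param conf_low_rate Fraction of frames given low tracking confidence
#'   (they are dropped by default QC).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(aus = default_au_set(),
                        baseline = 0.4,
                        noise_sd = 0.03,
                        ar_rho = 0.9,
                        event_rate_per_min = 3,
                        event_amp = 0.6,
                        event_amp_sd = 0.08,
                        event_dur_range = c(0.5, 2),
                        subject_amp_sd = 0.08,
                        gender_delta = c(M = -0.35, F = 0.4),
                        gender_first_trial_delta = c(M = -0.6, F = 0.7),
                        gender_first_trial_aus = c("AU14", "AU20"),
                        stimulus_au = "AU06",
                        stimulus_delta = c(blank = -0.35, own_face = 0.5,
                                           other_face = 0),
                        third_trial_delta = 0.4,
                        third_trial_aus = c("AU04", "AU17", "AU25"),
                        gaze_dwell = c(blank = 0.6, own_face = 0.85,
                                       other_face = 0.75),
                        gaze_gender_delta = c(M = 0.08, F = -0.08),
                        gaze_first_trial_delta = c(M = 0.15, F = -0.15),
                        gaze_sd_on = 0.05,
                        gaze_threshold = 0.1745,
                        conf_low_rate = 0.02) {
  stopifnot(length(aus) >= 1, all(gaze_dwell >= 0 & gaze_dwell <= 1),
            ar_rho >= 0, ar_rho < 1, noise_sd >= 0, event_amp >= 0,
            length(event_dur_range) == 2, event_dur_range[1] > 0,
            event_dur_range[2] >= event_dur_range[1], gaze_threshold > 0,
            conf_low_rate >= 0, conf_low_rate < 1)
  baseline <- rep_len(baseline, length(aus))
  names(baseline) <- aus
  structure(list(aus = aus, baseline = baseline, noise_sd = noise_sd,
                 ar_rho = ar_rho, event_rate_per_min = event_rate_per_min,
                 event_amp = event_amp, event_amp_sd = event_amp_sd,
                 event_dur_range = event_dur_range,
                 subject_amp_sd = subject_amp_sd,
                 gender_delta = gender_delta,
                 gender_first_trial_delta = gender_first_trial_delta,
                 gender_first_trial_aus = gender_first_trial_aus,
                 stimulus_au = stimulus_au, stimulus_delta = stimulus_delta,
                 third_trial_delta = third_trial_delta,
                 third_trial_aus = third_trial_aus,
                 gaze_dwell = gaze_dwell,
                 gaze_gender_delta = gaze_gender_delta,
                 gaze_first_trial_delta = gaze_first_trial_delta,
                 gaze_sd_on = gaze_sd_on, gaze_threshold = gaze_threshold,
                 conf_low_rate = conf_low_rate),
            class = "effect_spec")
}

#' Zero-effect variant of an effect specification
#'
#' All planted deltas and the subject random effect set to zero; dwell
#' probability equal across conditions. Useful for null calibration.
#'
#' @param effects An [effect_spec()] to neutralise.
#' @return An `effect_spec` with no planted structure.
#' @export
null_effect_spec <- function(effects = effect_spec()) {
  effects$gender_delta[] <- 0
  effects$gender_first_trial_delta[] <- 0
  effects$gaze_gender_delta[] <- 0
  effects$stimulus_delta[] <- 0
  effects$third_trial_delta <- 0
  effects$subject_amp_sd <- 0
  effects$gaze_dwell[] <- mean(effects$gaze_dwell)
  effects$gaze_first_trial_delta[] <- 0
  effects
}

# Event-amplitude delta for one AU in one trial
#' @noRd
planted_amp_delta <- function(au, gender, condition, trial_index, effects,
                              subject_amp) {
  delta <- subject_amp[[au]]
  if (au %in% effects$gender_first_trial_aus) {
    delta <- delta + effects$gender_delta[[gender]]
    if (trial_index == 1) {
      delta <- delta + effects$gender_first_trial_delta[[gender]]
    }
  }
  if (au == effects$stimulus_au) {
    delta <- delta + effects$stimulus_delta[[condition]]
  }
  if (au %in% effects$third_trial_aus && trial_index == 3) {
    delta <- delta + effects$third_trial_delta
  }
  delta
}

# One AU intensity series: baseline + AR(1) noise + raised-cosine events
#' @noRd
simulate_au_series <- function(n, fps, baseline, amp_mean, effects) {
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, effects$noise_sd),
                                    effects$ar_rho, method = "recursive"))
  x <- baseline + noise
  n_events <- stats::rpois(1, effects$event_rate_per_min * n / fps / 60)
  if (n_events > 0) {
    centers <- stats::runif(n_events, 1, n)
    durs <- stats::runif(n_events, effects$event_dur_range[1],
                         effects$event_dur_range[2]) * fps
    amps <- pmax(0, amp_mean + stats::rnorm(n_events, 0, effects$event_amp_sd))
    for (e in seq_len(n_events)) {
      lo <- max(1, floor(centers[e] - durs[e] / 2))
      hi <- min(n, ceiling(centers[e] + durs[e] / 2))
      idx <- lo:hi
      phase <- (idx - centers[e]) / durs[e]          # in [-0.5, 0.5]
      x[idx] <- x[idx] + amps[e] * 0.5 * (1 + cos(2 * pi * phase))
    }
  }
  clamp(x, 0, 5)
}

# Gaze angles: i.i.d. per-frame on-screen membership at probability p;
# on-screen magnitudes strictly below the threshold, off-screen above it.
#' @noRd
simulate_gaze <- function(n, p_on, effects) {
  on <- stats::runif(n) < p_on
  mag <- numeric(n)
  mag[on] <- clamp(abs(stats::rnorm(sum(on), 0, effects$gaze_sd_on)),
                   0, 0.95 * effects$gaze_threshold)
  mag[!on] <- stats::runif(sum(!on), 1.2 * effects$gaze_threshold,
                           3 * effects$gaze_threshold)
  theta <- stats::runif(n, 0, 2 * pi)
  list(x = mag * cos(theta), y = mag * sin(theta))
}

#' Generate a synthetic tracked cohort
#'
#' Simulates one OpenFace-style tracking table per eyes-open trial for the
#' whole design of `spec`, with the planted effects of `effects`, plus the
#' matching trial-annotation table and a ground-truth record (seed, spec
#' fingerprints, every planted effect). With the default spec this is
#' 18 x 3 x 3 = 162 trials of 3600 frames each. The same `spec$seed`
#' regenerates the cohort byte-for-byte.
#'
#' @param spec A [cohort_spec()].
#' @param effects An [effect_spec()].
#' @param dir Optional output directory; when given, one CSV per trial
#'   (named by [track_filename()]), `annotations.tsv` and
#'   `ground_truth.json` are written there.
#' @return Invisibly, a list: `tracks` (named list of `of_track` data
#'   frames keyed by trial id), `annotations`, `truth`.
#' @export
generate_cohort <- function(spec = cohort_spec(), effects = effect_spec(),
                            dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(effects, "effect_spec"))
  set.seed(spec$seed)
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  genders <- c(rep("M", spec$n_men), rep("F", spec$n_women))
  n <- as.integer(round(spec$trial_seconds * spec$fps))
  aus <- effects$aus

  # per-subject, per-AU amplitude random effect (individual specificity)
  subj_amp <- matrix(stats::rnorm(spec$n_subjects * length(aus), 0,
                                  effects$subject_amp_sd),
                     spec$n_subjects, length(aus),
                     dimnames = list(subjects, aus))

  ann <- expand.grid(trial_index = seq_len(spec$trials_per_condition),
                     condition = spec$conditions,
                     subject_id = subjects,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann <- ann[, c("subject_id", "condition", "trial_index")]
  ann$gender <- genders[match(ann$subject_id, subjects)]
  ann$start_frame <- 0L
  ann$end_frame <- n
  ann <- validate_annotations(ann)
  ann <- ann[, c("subject_id", "gender", "condition", "trial_index",
                 "start_frame", "end_frame", "trial_id")]

  tracks <- vector("list", nrow(ann))
  names(tracks) <- ann$trial_id
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    amp_row <- subj_amp[a$subject_id, ]
    track <- data.frame(
      frame = 0:(n - 1L),
      timestamp = (0:(n - 1L)) / spec$fps,
      confidence = ifelse(stats::runif(n) < effects$conf_low_rate,
                          stats::runif(n, 0.3, 0.7),
                          stats::runif(n, 0.85, 0.99)),
      success = TRUE
    )
    p_on <- clamp(effects$gaze_dwell[[a$condition]] +
                    effects$gaze_gender_delta[[a$gender]] +
                    if (a$trial_index == 1)
                      effects$gaze_first_trial_delta[[a$gender]] else 0,
                  0, 1)
    g <- simulate_gaze(n, p_on, effects)
    track$gaze_angle_x <- g$x
    track$gaze_angle_y <- g$y
    for (au in aus) {
      amp <- effects$event_amp +
        planted_amp_delta(au, a$gender, a$condition, a$trial_index, effects,
                          amp_row)
      track[[au]] <- simulate_au_series(n, spec$fps, effects$baseline[[au]],
                                        amp, effects)
    }
    tracks[[i]] <- structure(track, au_codes = aus,
                             class = c("of_track", "data.frame"))
  }

  truth <- list(
    seed = spec$seed,
    spec_hash = config_hash(unclass(spec)),
    effects_hash = config_hash(unclass(effects)),
    design = list(n_subjects = spec$n_subjects, n_men = spec$n_men,
                  n_women = spec$n_women, conditions = spec$conditions,
                  trials_per_condition = spec$trials_per_condition,
                  frames_per_trial = n),
    planted = list(
      gender = list(aus = effects$gender_first_trial_aus,
                    delta = effects$gender_delta),
      gender_first_trial = list(aus = effects$gender_first_trial_aus,
                                delta = effects$gender_first_trial_delta),
      gaze_gender = effects$gaze_gender_delta,
      stimulus = list(au = effects$stimulus_au,
                      delta = effects$stimulus_delta),
      third_trial = list(aus = effects$third_trial_aus,
                         delta = effects$third_trial_delta),
      gaze_dwell = effects$gaze_dwell,
      gaze_first_trial = effects$gaze_first_trial_delta,
      subject_amp_sd = effects$subject_amp_sd)
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      tr <- tracks[[i]]
      out <- tr
      names(out) <- c(names(out)[1:6], paste0(aus, "_r"))
      utils::write.csv(format(out, digits = 6, trim = TRUE, scientific = FALSE),
                       file.path(dir, track_filename(a$subject_id, a$condition,
                                                     a$trial_index)),
                       row.names = FALSE, quote = FALSE)
    }
    write_tsv(ann[, setdiff(names(ann), "trial_id")],
              file.path(dir, "annotations.tsv"))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tracks = tracks, annotations = ann, truth = truth))
}

#' Generate paired blocks with one planted latent structure
#'
#' Block-level shortcut for statistical validation: a shared standard-normal
#' latent score `t` is propagated into both blocks along planted unit weight
#' vectors (`b1 = snr * t u' + E1`, likewise for `b2`), with independent
#' unit-variance Gaussian noise. `snr` is the sd of the signal along the
#' planted direction relative to the per-entry noise sd; `snr = 0` gives
#' pure noise.
#'
#' @param n Number of objects (>= 10).
#' @param p1,p2 Block widths (used when `u`/`v` are not supplied).
#' @param u,v Optional planted unit weight vectors (length p1, p2).
#' @param snr Signal-to-noise amplitude (default 2).
#' @param seed RNG seed.
#' @return List: `b1`, `b2` (matrices) and `truth` (`u`, `v`, `t`, `snr`).
#' @export
generate_blocks <- function(n, p1 = 13, p2 = 26, u = NULL, v = NULL,
                            snr = 2, seed = NULL) {
  stopifnot(n >= 10, snr >= 0)
  if (!is.null(seed)) set.seed(seed)
  unitize <- function(w) w / sqrt(sum(w^2))
  u <- if (is.null(u)) unitize(stats::rnorm(p1)) else unitize(u)
  v <- if (is.null(v)) unitize(stats::rnorm(p2)) else unitize(v)
  p1 <- length(u); p2 <- length(v)
  t_lat <- stats::rnorm(n)
  b1 <- snr * tcrossprod(t_lat, u) + matrix(stats::rnorm(n * p1), n, p1)
  b2 <- snr * tcrossprod(t_lat, v) + matrix(stats::rnorm(n * p2), n, p2)
  colnames(b1) <- paste0("x", seq_len(p1))
  colnames(b2) <- paste0("y", seq_len(p2))
  list(b1 = b1, b2 = b2, truth = list(u = u, v = v, t = t_lat, snr = snr))
}
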