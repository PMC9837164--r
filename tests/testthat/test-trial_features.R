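test_that("au_range is max minus min and rejects empty input", {
  expect_equal(au_range(c(0.2, 0.2, 0.2)), 0)
  expect_equal(au_range(c(0.1, 0.5, 0.3)), 0.4)
  expect_error(au_range(numeric(0)), "insufficient")
})

test_that("au_range recovers a planted spike amplitude in a long series", {
  # baseline 1.0 with a single spike to 3.2: range must be found by a full
  # scan, not by any summary of typical values
  set.seed(11)
  x <- rep(1.0, 1000)
  x[sample.int(1000, 1)] <- 3.2
  # independent brute-force scan
  mx <- -Inf; mn <- Inf
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  expect_equal(mx - mn, 2.2)
  expect_equal(au_range(x), 2.2)
})

test_that("au_range is translation-invariant and scales linearly", {
  set.seed(3)
  for (i in 1:25) {
    x <- runif(50, 0, 5)
    shift <- runif(1, -2, 2)
    fac <- runif(1, 0.1, 3)
    expect_equal(au_range(x + shift), au_range(x))
    expect_equal(au_range(fac * x), fac * au_range(x))
  }
})

test_that("gaze_on_screen_prop counts frames inside the angular cone", {
  tr <- make_track(n = 10, gaze_x = 0, gaze_y = 0)
  expect_equal(gaze_on_screen_prop(tr, gaze_config(0.05)), 1)

  mag <- c(rep(0.05, 4), rep(0.4, 6))
  tr2 <- make_track(n = 10, gaze_x = mag, gaze_y = 0)
  expect_equal(gaze_on_screen_prop(tr2, gaze_config(0.1745)), 0.4)

  expect_error(gaze_on_screen_prop(make_track(n = 0)), "insufficient")
})

test_that("gaze_on_screen_prop is monotone in the threshold", {
  set.seed(5)
  tr <- make_track(n = 200, gaze_x = rnorm(200, 0, 0.2),
                   gaze_y = rnorm(200, 0, 0.2))
  thresholds <- seq(0.01, 0.6, by = 0.01)
  props <- vapply(thresholds, function(th)
    gaze_on_screen_prop(tr, gaze_config(th)), numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("generated gaze dwell matches its planted probability", {
  # one 200-second trial at 30 fps = 6000 frames with dwell 0.7 planted;
  # the observed on-screen proportion is a binomial mean within 0.7 +/- 0.02
  eff <- effect_spec(gaze_dwell = c(blank = 0.7, own_face = 0.7,
                                    other_face = 0.7),
                     gaze_gender_delta = c(M = 0, F = 0),
                     gaze_first_trial_delta = c(M = 0, F = 0))
  spec <- cohort_spec(n_subjects = 1, n_men = 1, n_women = 0,
                      conditions = "blank", trials_per_condition = 1,
                      trial_seconds = 200, fps = 30, seed = 99)
  co <- generate_cohort(spec, eff)
  tr <- co$tracks[[1]]
  expect_equal(nrow(tr), 6000)
  p <- gaze_on_screen_prop(tr, gaze_config(eff$gaze_threshold))
  expect_true(abs(p - 0.7) <= 0.02)
})

test_that("extract_trial_features yields 13 instrumental values per trial", {
  set.seed(21)
  co <- generate_cohort(cohort_spec(n_subjects = 1, n_men = 0, n_women = 1,
                                    conditions = "own_face",
                                    trials_per_condition = 1,
                                    trial_seconds = 20, fps = 50, seed = 4))
  tr <- filter_frames(co$tracks[[1]], qc_config())
  row <- extract_trial_features(tr, co$annotations[1, ],
                                qc = qc_config(min_frames = 100))
  vals <- c(row$gaze_on_screen_prop,
            unlist(row[paste0(default_au_set(), "_range")]))
  expect_length(vals, 13)
  expect_false(row$excluded)
  expect_true(all(vals >= 0 & vals <= 5))
})

test_that("trials below the frame floor are flagged excluded, not dropped", {
  tr <- make_track(n = 0, aus = default_au_set())
  ann <- list(subject_id = "S01", gender = "F", condition = "blank",
              trial_index = 1L)
  row <- extract_trial_features(tr, ann, qc = qc_config(min_frames = 10),
                                aus = default_au_set())
  expect_true(row$excluded)
  expect_true(is.na(row$gaze_on_screen_prop))
})

test_that("feature extraction is deterministic under a fixed seed", {
  spec <- cohort_spec(n_subjects = 2, n_men = 1, n_women = 1,
                      trial_seconds = 12, seed = 123)
  f1 <- cohort_features(generate_cohort(spec)$tracks,
                        generate_cohort(spec)$annotations,
                        qc = qc_config(min_frames = 100))
  f2 <- cohort_features(generate_cohort(spec)$tracks,
                        generate_cohort(spec)$annotations,
                        qc = qc_config(min_frames = 100))
  expect_identical(f1, f2)
})

test_that("low retained fraction excludes a trial from the feature table", {
  set.seed(9)
  tr <- make_track(n = 400, aus = default_au_set(),
                   confidence = c(rep(0.5, 300), rep(0.95, 100)))
  ann <- make_annotations(subjects = "S01", genders = "M",
                          conditions = "blank", trials = 1, n_frames = 400)
  fe <- cohort_features(stats::setNames(list(tr), "S01.blank.1"), ann,
                        qc = qc_config(min_frames = 50, min_retained = 0.5))
  expect_true(fe$excluded[1])
  expect_lt(fe$retained_fraction[1], 0.5)
})
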