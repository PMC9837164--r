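#' One-hot design-feature block
#'
#' Encodes the experimental design of each trial as binary indicator columns:
#' one per subject (individual specificity), per gender, per stimulus type
#' (`blank`, `own_face`, `other_face`) and per trial position (first, second,
#' third). With the full 18-subject design this yields 18 + 2 + 3 + 3 = 26
#' feature variables — a reconstruction of the published block composition
#' that reproduces its printed column count and contains every feature the
#' fitted structures are interpreted on. Redundant one-hot groups (both
#' genders, all three conditions) are deliberately kept rather than reduced
#' to reference coding: the decomposition tolerates exactly collinear
#' columns, and the full coding keeps every loading directly interpretable.
#'
#' @param annotations Annotation data frame (one row per trial).
#' @return Binary matrix of class `feature_block`, rows named by `trial_id`,
#'   with the coding scheme in `attr(x, "scheme")`.
#' @export
encode_features <- function(annotations) {
  if (!("trial_id" %in% names(annotations))) {
    annotations <- validate_annotations(annotations)
  }
  subjects <- sort(unique(annotations$subject_id))
  genders <- c("M", "F")
  conditions <- c("blank", "own_face", "other_face")
  trials <- 1:3
  cols <- c(paste0("subject_", subjects), paste0("gender_", genders),
            paste0("cond_", conditions), paste0("trial_", trials))
  m <- matrix(0L, nrow(annotations), length(cols),
              dimnames = list(annotations$trial_id, cols))
  m[cbind(seq_len(nrow(m)), match(paste0("subject_", annotations$subject_id), cols))] <- 1L
  m[cbind(seq_len(nrow(m)), match(paste0("gender_", annotations$gender), cols))] <- 1L
  m[cbind(seq_len(nrow(m)), match(paste0("cond_", annotations$condition), cols))] <- 1L
  m[cbind(seq_len(nrow(m)), match(paste0("trial_", annotations$trial_index), cols))] <- 1L
  structure(m,
            scheme = list(subjects = subjects, genders = genders,
                          conditions = conditions, trial_positions = trials),
            class = c("feature_block", class(m)))
}

#' Align the instrumental and feature blocks
#'
#' Builds the instrumental block (gaze-on-screen proportion + AU ranges) from
#' a trial-feature table and pairs it row-by-row with the encoded feature
#' block. Excluded trials (and any trial with missing features) are removed
#' from BOTH blocks so the rows stay paired; with the full design, 18
#' subjects x 3 conditions x 3 eyes-open trials give 162 rows.
#'
#' @param features `trial_features` data frame from [cohort_features()].
#' @param encoded `feature_block` matrix from [encode_features()].
#' @param aus AU codes expected in the instrumental set, in column order;
#'   default inferred from the feature table's `<AU>_range` columns.
#' @return List with `b1` (instrumental matrix, class `instrumental_block`),
#'   `b2` (feature matrix), `trial_ids`, and `dropped` (ids removed).
#' @export
align_blocks <- function(features, encoded, aus = NULL) {
  stopifnot(inherits(encoded, "feature_block"))
  if (is.null(aus)) {
    aus <- sub("_range$", "", grep("_range$", names(features), value = TRUE))
  }
  cols <- c("gaze_on_screen_prop", paste0(aus, "_range"))
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  usable <- !features$excluded &
    stats::complete.cases(features[, cols, drop = FALSE])
  keep_ids <- intersect(rownames(encoded), features$trial_id[usable])
  if (length(keep_ids) == 0) {
    stop("block alignment failed: no usable trials shared by the two blocks")
  }
  # preserve the encoded (annotation) row order
  keep_ids <- rownames(encoded)[rownames(encoded) %in% keep_ids]
  fidx <- match(keep_ids, features$trial_id)
  if (anyNA(fidx)) stop("block alignment failed: row-id mismatch")
  b1 <- as.matrix(features[fidx, cols, drop = FALSE])
  rownames(b1) <- keep_ids
  b2 <- encoded[keep_ids, , drop = FALSE]
  if (!identical(rownames(b1), rownames(b2))) {
    stop("block alignment failed: row-id mismatch after assembly")
  }
  dropped <- setdiff(union(features$trial_id, rownames(encoded)), keep_ids)
  list(b1 = structure(b1, class = c("instrumental_block", class(b1))),
       b2 = structure(b2, scheme = attr(encoded, "scheme"),
                      class = c("feature_block", "matrix", "array")),
       trial_ids = keep_ids, dropped = dropped)
}

#' Write aligned blocks as TSV plus a JSON coding sidecar
#'
#' @param blocks Result of [align_blocks()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_blocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "block_b1.tsv")
  p2 <- file.path(dir, "block_b2.tsv")
  ps <- file.path(dir, "coding_scheme.json")
  write_matrix_tsv(blocks$b1, p1, id_col = "trial_id")
  write_matrix_tsv(blocks$b2, p2, id_col = "trial_id")
  jsonlite::write_json(attr(blocks$b2, "scheme"), ps, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(p1, p2, ps))
}
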