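#' Default instrumental AU set
#'
#' The twelve action units whose per-trial expression ranges form, together
#' with the gaze-on-screen proportion, the 13-variable instrumental block.
#' The set covers the muscles discussed with the fitted structures (inner and
#' outer brow raiser, brow lowerer / depressor glabellae, cheek raiser, nose
#' wrinkler, upper lip raiser, lip corner puller, dimpler/buccinator, lip
#' corner depressor, chin raiser, risorius, lips part). It is a documented
#' reconstruction, not a canon: pass your own `aus` to the feature and
#' pipeline functions to change it.
#'
#' @return Character vector of normalised AU codes ("AU01", ...).
#' @export
#' @examples
#' default_au_set()
default_au_set <- function() {
  c("AU01", "AU02", "AU04", "AU06", "AU09", "AU10",
    "AU12", "AU14", "AU15", "AU17", "AU20", "AU25")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a over a string; returns 8 hex digits. Used to fingerprint specs and
# configs in run reports so reruns can be matched to their inputs.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double to stay 32-bit
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, in doubles.
    # Split h to keep every intermediate below 2^53.
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  # format as 8 hex digits; h may exceed .Machine$integer.max, so split
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Stable fingerprint of an R list (configs, specs)
config_hash <- function(x) {
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE))
}

log_line <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

# Canonical trial identifier used to key tracks and block rows
trial_id <- function(subject_id, condition, trial_index) {
  paste(subject_id, condition, trial_index, sep = ".")
}

#' Conventional file name of a trial's tracking CSV
#'
#' The simulator writes, and the pipeline reads, one tracking CSV per trial
#' named `<subject>_<condition>_trial<k>.csv` inside the input directory.
#'
#' @param subject_id Subject identifier string.
#' @param condition Stimulus condition (`"blank"`, `"own_face"`, `"other_face"`).
#' @param trial_index Trial position within condition (1, 2 or 3).
#' @return File name (no directory).
#' @export
track_filename <- function(subject_id, condition, trial_index) {
  sprintf("%s_%s_trial%d.csv", subject_id, condition, as.integer(trial_index))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

write_matrix_tsv <- function(m, path, id_col = "row_id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
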