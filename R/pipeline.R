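#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end pipeline. Can also be loaded from a
#' YAML file with [read_run_config()].
#'
#' @param input_dir Directory with one tracking CSV per trial.
#' @param annotations Path to the trial-annotation TSV.
#' @param output_dir Directory for all outputs (created if needed).
#' @param min_confidence,min_retained,min_frames See [qc_config()].
#' @param gaze_threshold See [gaze_config()].
#' @param aus Instrumental AU set; default [default_au_set()].
#' @param mode Block preprocessing, `"center_scale"` or `"center"`.
#' @param alpha Significance level for loading masks.
#' @param n_perm Permutation count for the structure-1 null (0 = off).
#' @param seed Seed for the permutation null.
#' @param loading_pairs List of structure pairs to export as paired loading
#'   tables; default structures (1,2) and (3,4).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, annotations, output_dir,
                       min_confidence = 0.75, min_retained = 0.5,
                       min_frames = 300L, gaze_threshold = 0.1745,
                       aus = default_au_set(),
                       mode = c("center_scale", "center"),
                       alpha = 0.05, n_perm = 0L, seed = 1L,
                       loading_pairs = list(c(1L, 2L), c(3L, 4L))) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 0)
  structure(list(input_dir = input_dir, annotations = annotations,
                 output_dir = output_dir,
                 qc = qc_config(min_confidence, min_retained, min_frames),
                 gaze = gaze_config(gaze_threshold),
                 aus = aus, mode = mode, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 loading_pairs = loading_pairs),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$loading_pairs)) {
    y$loading_pairs <- lapply(y$loading_pairs, as.integer)
  }
  do.call(run_config, y)
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Reads and quality-filters every annotated trial's tracking CSV, computes
#' the trial-feature table, assembles and aligns the two blocks, fits the
#' 2B-PLS model, and writes all outputs into `config$output_dir`:
#' `features.tsv`, `block_b1.tsv` / `block_b2.tsv` / `coding_scheme.json`,
#' the model dump of [write_pls_model()] (including `scree.tsv`), one paired
#' loading table per requested structure pair
#' (`loadings_pair_<i>_<j>.tsv`: variable, block, loadings on both
#' structures, significance flags), and `run_report.json` with counts,
#' exclusions, block shapes, seeds and a config fingerprint. Outputs are
#' deterministic: identical config and inputs reproduce them byte for byte.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param verbose Log progress to stderr?
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage("validate", {
    if (!dir.exists(config$input_dir)) {
      stop("input directory not found: ", config$input_dir)
    }
    if (!file.exists(config$annotations)) {
      stop("annotation file not found: ", config$annotations)
    }
  })
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- stage("annotations", read_annotations(config$annotations))
  if (verbose) log_line("read %d trial annotations", nrow(ann))

  features <- stage("features",
    cohort_features(config$input_dir, ann, qc = config$qc, gaze = config$gaze,
                    aus = config$aus, verbose = FALSE))
  write_features(features, file.path(config$output_dir, "features.tsv"))
  n_excluded <- sum(features$excluded)
  if (verbose) {
    log_line("extracted features for %d trials (%d excluded)",
             nrow(features), n_excluded)
  }

  blocks <- stage("blocks", {
    enc <- encode_features(ann)
    align_blocks(features, enc, aus = config$aus)
  })
  write_blocks(blocks, config$output_dir)
  if (verbose) {
    log_line("aligned blocks: %d x %d and %d x %d", nrow(blocks$b1),
             ncol(blocks$b1), nrow(blocks$b2), ncol(blocks$b2))
  }

  model <- stage("fit",
    pls2b(blocks$b1, blocks$b2, mode = config$mode, alpha = config$alpha,
          n_perm = config$n_perm, seed = config$seed))
  write_pls_model(model, config$output_dir)
  stage("report", {
    for (pair in config$loading_pairs) {
      write_loading_pair(model, pair, config$output_dir)
    }
  })
  if (verbose) {
    log_line("fitted 2B-PLS: %d latent structures, structure 1 share %.1f%%",
             length(model$singular_values), 100 * model$variance_share[1])
  }

  report <- list(
    n_annotations = nrow(ann),
    n_trials_ingested = nrow(features),
    n_trials_excluded = n_excluded,
    excluded_trial_ids = features$trial_id[features$excluded],
    block_shape = list(n = nrow(blocks$b1),
                       p1 = ncol(blocks$b1), p2 = ncol(blocks$b2)),
    n_structures = length(model$singular_values),
    variance_share = model$variance_share,
    alpha = config$alpha,
    critical_r = critical_r(model$n_objects, config$alpha),
    seed = config$seed,
    n_perm = config$n_perm,
    config_hash = config_hash(run_config_fingerprint(config)),
    complete = TRUE
  )
  jsonlite::write_json(report, file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @noRd
run_config_fingerprint <- function(config) {
  list(qc = unclass(config$qc), gaze = unclass(config$gaze),
       aus = config$aus, mode = config$mode, alpha = config$alpha,
       n_perm = config$n_perm, seed = config$seed,
       loading_pairs = config$loading_pairs)
}

#' Paired loading table for two latent structures
#'
#' One row per variable of both blocks with its correlation loadings on the
#' two structures and their significance flags — the plot-ready form of a
#' paired loading figure, on which the non-significant region is the square
#' of half-width [critical_r()] around the origin.
#'
#' @param model A `pls2b` model.
#' @param pair Integer pair of structure indices, e.g. `c(1, 2)`.
#' @param dir Optional directory; when given the table is written to
#'   `loadings_pair_<i>_<j>.tsv`.
#' @return The table (invisibly when written).
#' @export
write_loading_pair <- function(model, pair = c(1L, 2L), dir = NULL) {
  stopifnot(inherits(model, "pls2b"), length(pair) == 2)
  k <- length(model$singular_values)
  if (any(pair < 1 | pair > k)) {
    stop("structure pair out of range 1..", k)
  }
  tab <- rbind(
    data.frame(variable = rownames(model$corr_loadings_b1),
               block = "instrumental",
               x = model$corr_loadings_b1[, pair[1]],
               y = model$corr_loadings_b1[, pair[2]],
               sig_x = model$sig_mask_b1[, pair[1]],
               sig_y = model$sig_mask_b1[, pair[2]],
               stringsAsFactors = FALSE),
    data.frame(variable = rownames(model$corr_loadings_b2),
               block = "feature",
               x = model$corr_loadings_b2[, pair[1]],
               y = model$corr_loadings_b2[, pair[2]],
               sig_x = model$sig_mask_b2[, pair[1]],
               sig_y = model$sig_mask_b2[, pair[2]],
               stringsAsFactors = FALSE))
  names(tab)[3:6] <- c(paste0("LS", pair[1]), paste0("LS", pair[2]),
                       paste0("sig_LS", pair[1]), paste0("sig_LS", pair[2]))
  rownames(tab) <- NULL
  if (!is.null(dir)) {
    write_tsv(tab, file.path(dir, sprintf("loadings_pair_%d_%d.tsv",
                                          pair[1], pair[2])))
    return(invisible(tab))
  }
  tab
}
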