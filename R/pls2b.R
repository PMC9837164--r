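#' Center (and optionally scale) a block
#'
#' Columns are mean-centered; in `center_scale` mode each is also divided by
#' its standard deviation. Zero-variance columns are left centered (all
#' zeros) and flagged rather than producing NaNs — with binary design
#' indicators a constant column just means a level that never varies in the
#' data at hand.
#'
#' @param x Numeric matrix (objects x variables), no missing values, at
#'   least 3 rows.
#' @param mode `"center"` or `"center_scale"`.
#' @return List: `x` (preprocessed matrix), `center`, `scale` (1 for
#'   unscaled/constant columns), `constant` (logical flag per column),
#'   `mode`.
#' @export
pls_preprocess <- function(x, mode = c("center_scale", "center")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (anyNA(x)) stop("preprocessing failed: block contains missing values")
  if (nrow(x) < 3) stop("insufficient objects: need at least 3 rows")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr, "-")
  sds <- apply(xc, 2, stats::sd)
  constant <- sds < .Machine$double.eps^0.5
  scl <- rep(1, ncol(x))
  if (mode == "center_scale") {
    scl[!constant] <- sds[!constant]
    xc <- sweep(xc, 2, scl, "/")
  }
  list(x = xc, center = ctr, scale = scl, constant = constant, mode = mode)
}

#' Fit a two-block partial least squares (2B-PLS) model
#'
#' Finds pairs of axes — latent structures — one per block, that maximise the
#' covariance between the two blocks' projected scores. Both blocks are
#' centered (and by default scaled, since a binary feature block has far
#' smaller variance than an instrumental block); the cross-product matrix of
#' the preprocessed blocks is decomposed by one SVD, whose left and right
#' singular vectors are the orthonormal weight (loading) matrices and whose
#' singular values order the structures by covariance explained. This
#' one-shot SVD is the symmetric two-block (inter-battery) form; it
#' coincides with iterative NIPALS-with-deflation for this case and is
#' deterministic. The number of structures is `min(p1, p2)`; the method is
#' indifferent to more variables than objects and to exactly collinear
#' columns in either block.
#'
#' The sign of each structure is fixed so the largest-magnitude element of
#' the block-1 weight vector is positive, making results reproducible.
#'
#' @param b1,b2 Numeric matrices with the same rows (objects; trials). Row
#'   names, when present, must agree.
#' @param mode Preprocessing per block: `"center_scale"` (default) or
#'   `"center"`.
#' @param alpha Two-sided significance level for the correlation-loading
#'   mask (default 0.05).
#' @param n_perm If > 0, additionally build a permutation null for the first
#'   structure's variance share by refitting after row-shuffling block 2
#'   (`n_perm` shuffles, seeded by `seed`).
#' @param seed RNG seed for the permutation null.
#' @return An object of class `pls2b`: weight matrices `weights_b1`
#'   (p1 x K), `weights_b2` (p2 x K), score matrices `scores_b1`,
#'   `scores_b2` (n x K), `singular_values` (K, non-increasing),
#'   `variance_share` (K, sums to 1), correlation loadings and significance
#'   masks per block, `n_objects`, `alpha`, a `preprocessing` record (mode,
#'   centers, scales, constant-column flags, and the score-covariance
#'   convention `cov(t1_k, t2_k) = d_k / (n - 1)`), and optionally `perm`
#'   (null shares and a p-value for structure 1).
#' @export
#' @examples
#' set.seed(1)
#' sim <- generate_blocks(n = 60, p1 = 5, p2 = 8, snr = 2, seed = 1)
#' fit <- pls2b(sim$b1, sim$b2)
#' fit
pls2b <- function(b1, b2, mode = c("center_scale", "center"), alpha = 0.05,
                  n_perm = 0, seed = NULL) {
  mode <- match.arg(mode)
  b1 <- as.matrix(b1); b2 <- as.matrix(b2)
  if (nrow(b1) != nrow(b2)) stop("blocks have different numbers of objects")
  if (!is.null(rownames(b1)) && !is.null(rownames(b2)) &&
      !identical(rownames(b1), rownames(b2))) {
    stop("block row names disagree; align the blocks first")
  }
  if (anyNA(b1) || anyNA(b2)) stop("data error: blocks contain missing values")
  n <- nrow(b1)
  if (n < 3) stop("insufficient objects: need at least 3 rows")

  prep1 <- pls_preprocess(b1, mode)
  prep2 <- pls_preprocess(b2, mode)
  core <- pls2b_core(prep1$x, prep2$x)

  cl1 <- block_score_correlations(b1, core$scores_b1)
  cl2 <- block_score_correlations(b2, core$scores_b2)

  model <- structure(list(
    weights_b1 = core$weights_b1, weights_b2 = core$weights_b2,
    scores_b1 = core$scores_b1, scores_b2 = core$scores_b2,
    singular_values = core$d,
    variance_share = variance_shares(core$d),
    corr_loadings_b1 = cl1$r, corr_loadings_b2 = cl2$r,
    constant_b1 = cl1$constant, constant_b2 = cl2$constant,
    sig_mask_b1 = significance_mask(cl1$r, n, alpha),
    sig_mask_b2 = significance_mask(cl2$r, n, alpha),
    n_objects = n, alpha = alpha,
    preprocessing = list(
      mode = mode,
      center_b1 = prep1$center, scale_b1 = prep1$scale,
      constant_b1 = prep1$constant,
      center_b2 = prep2$center, scale_b2 = prep2$scale,
      constant_b2 = prep2$constant,
      decomposition = "svd of crossprod(X1, X2) (one-shot two-block PLS)",
      score_covariance = "cov(t1_k, t2_k) = d_k / (n - 1)"),
    call = match.call()
  ), class = "pls2b")

  if (n_perm > 0) {
    model$perm <- pls2b_permutation_null(prep1$x, prep2$x,
                                         observed_share = model$variance_share[1],
                                         n_perm = n_perm, seed = seed)
  }
  model
}

# SVD engine on preprocessed blocks; sign convention applied here.
#' @noRd
pls2b_core <- function(x1, x2) {
  k <- min(ncol(x1), ncol(x2))
  cp <- crossprod(x1, x2)
  sv <- svd(cp, nu = k, nv = k)
  u <- sv$u; v <- sv$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  dimnames(u) <- list(colnames(x1), paste0("LS", seq_len(k)))
  dimnames(v) <- list(colnames(x2), paste0("LS", seq_len(k)))
  t1 <- x1 %*% u; t2 <- x2 %*% v
  rownames(t1) <- rownames(x1); rownames(t2) <- rownames(x2)
  list(weights_b1 = u, weights_b2 = v, scores_b1 = t1, scores_b2 = t2,
       d = sv$d[seq_len(k)])
}

#' Variance shares of the latent structures
#'
#' Each structure's squared singular value as a fraction of the total across
#' structures — the scree-plot quantity: the share of the observed total
#' (cross-block) variance a structure describes.
#'
#' @param d Either a `pls2b` model or its vector of singular values.
#' @return Numeric vector of proportions summing to 1, non-increasing.
#' @export
variance_shares <- function(d) {
  if (inherits(d, "pls2b")) d <- d$singular_values
  stopifnot(is.numeric(d), length(d) >= 1, all(d >= 0))
  tot <- sum(d^2)
  if (tot == 0) stop("variance shares undefined: all singular values are zero")
  d^2 / tot
}

# Pearson correlation of each original column with each score column;
# constant columns get 0 and a flag.
#' @noRd
block_score_correlations <- function(block, scores) {
  block <- as.matrix(block)
  constant <- apply(block, 2, function(col) stats::sd(col) < .Machine$double.eps^0.5)
  r <- matrix(0, ncol(block), ncol(scores),
              dimnames = list(colnames(block), colnames(scores)))
  if (any(!constant)) {
    r[!constant, ] <- suppressWarnings(
      stats::cor(block[, !constant, drop = FALSE], scores))
  }
  r[is.na(r)] <- 0
  list(r = r, constant = constant)
}

#' Correlation loadings of the original variables
#'
#' The Pearson correlation of each original (un-preprocessed) variable with
#' its own block's latent score, per structure — the quantity shown on
#' paired loading plots. Unlike the weights it is invariant to whether the
#' scores are rescaled, which makes it the comparable reported quantity.
#'
#' @param model A fitted `pls2b` model.
#' @param b1,b2 The original blocks the model was fitted to.
#' @return List with matrices `corr_loadings_b1` (p1 x K) and
#'   `corr_loadings_b2` (p2 x K), entries in \[-1, 1\]; constant variables
#'   are flagged and set to 0.
#' @export
correlation_loadings <- function(model, b1, b2) {
  stopifnot(inherits(model, "pls2b"))
  cl1 <- block_score_correlations(b1, model$scores_b1)
  cl2 <- block_score_correlations(b2, model$scores_b2)
  list(corr_loadings_b1 = cl1$r, corr_loadings_b2 = cl2$r,
       constant_b1 = cl1$constant, constant_b2 = cl2$constant)
}

#' Significance mask for correlation loadings
#'
#' Two-sided t-test of a Pearson correlation against zero with n - 2 degrees
#' of freedom, `t = r * sqrt((n - 2) / (1 - r^2))`; an entry is `TRUE`
#' (significant) when p <= alpha. `|r| = 1` is significant by convention
#' (p -> 0). On a loading plot the non-significant region is the rectangle
#' `|r| < critical_r(n, alpha)` around the origin.
#'
#' @param r Matrix (or vector) of correlations in \[-1, 1\].
#' @param n_objects Number of objects the correlations were computed from
#'   (>= 4).
#' @param alpha Two-sided significance level.
#' @return Logical matrix (or vector) shaped like `r`.
#' @export
significance_mask <- function(r, n_objects, alpha = 0.05) {
  stopifnot(n_objects >= 4, alpha > 0, alpha < 1)
  rr <- pmin(abs(r), 1)
  p <- ifelse(rr >= 1, 0,
              2 * stats::pt(rr * sqrt((n_objects - 2) / (1 - rr^2)),
                            df = n_objects - 2, lower.tail = FALSE))
  mask <- p <= alpha
  if (is.matrix(r)) dimnames(mask) <- dimnames(r)
  mask
}

#' Critical correlation at a given significance level
#'
#' The |r| at which the two-sided t-test on a Pearson correlation with
#' n - 2 degrees of freedom crosses `alpha` — the half-width of the
#' non-significance rectangle on a loading plot.
#'
#' @param n_objects Number of objects (>= 4).
#' @param alpha Two-sided significance level.
#' @return The critical |r| in (0, 1).
#' @export
critical_r <- function(n_objects, alpha = 0.05) {
  stopifnot(n_objects >= 4, alpha > 0, alpha < 1)
  tq <- stats::qt(1 - alpha / 2, df = n_objects - 2)
  tq / sqrt(n_objects - 2 + tq^2)
}

# Permutation null for the first structure's variance share: row-shuffle the
# preprocessed second block, refit, record share 1.
#' @noRd
pls2b_permutation_null <- function(x1, x2, observed_share, n_perm = 999,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x2)
  null_share <- vapply(seq_len(n_perm), function(i) {
    d <- pls2b_core(x1, x2[sample.int(n), , drop = FALSE])$d
    d[1]^2 / sum(d^2)
  }, numeric(1))
  list(n_perm = n_perm, null_share = null_share,
       p_value = (1 + sum(null_share >= observed_share)) / (n_perm + 1))
}

#' @export
print.pls2b <- function(x, ...) {
  k <- length(x$singular_values)
  cat("Two-block PLS model\n")
  cat(sprintf("  objects: %d   block sizes: %d x %d   latent structures: %d\n",
              x$n_objects, nrow(x$weights_b1), nrow(x$weights_b2), k))
  cat(sprintf("  preprocessing: %s\n", x$preprocessing$mode))
  shares <- x$variance_share
  show <- seq_len(min(4, k))
  cat("  variance shares:",
      paste(sprintf("LS%d %.1f%%", show, 100 * shares[show]), collapse = ", "),
      if (k > 4) "..." else "", "\n")
  if (!is.null(x$perm)) {
    cat(sprintf("  permutation p-value (structure 1 share): %.4f (%d shuffles)\n",
                x$perm$p_value, x$perm$n_perm))
  }
  invisible(x)
}

#' Scree table of a fitted model
#'
#' @param model A `pls2b` model.
#' @return Data frame with `structure` (1..K) and `variance_share`, ready
#'   for a scree plot.
#' @export
scree_table <- function(model) {
  stopifnot(inherits(model, "pls2b"))
  data.frame(structure = seq_along(model$variance_share),
             variance_share = model$variance_share)
}

#' Scree plot of a fitted model
#'
#' @param x A `pls2b` model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pls2b <- function(x, ...) {
  st <- scree_table(x)
  graphics::plot(st$structure, 100 * st$variance_share, type = "b",
                 xlab = "latent structure",
                 ylab = "share of total variance (%)", ...)
  invisible(x)
}

#' Export a fitted model as JSON metadata plus TSV matrices
#'
#' Writes `model.json` (sizes, preprocessing record, singular values,
#' variance shares, alpha, permutation summary if present) and one TSV per
#' matrix: weights, scores, correlation loadings and significance masks for
#' both blocks, plus `scree.tsv`.
#'
#' @param model A `pls2b` model.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_pls_model <- function(model, dir) {
  stopifnot(inherits(model, "pls2b"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n_objects = model$n_objects,
    p1 = nrow(model$weights_b1), p2 = nrow(model$weights_b2),
    n_structures = length(model$singular_values),
    singular_values = model$singular_values,
    variance_share = model$variance_share,
    alpha = model$alpha,
    critical_r = critical_r(model$n_objects, model$alpha),
    preprocessing = model$preprocessing[c("mode", "decomposition",
                                          "score_covariance")]
  )
  if (!is.null(model$perm)) {
    meta$permutation <- list(n_perm = model$perm$n_perm,
                             p_value_structure1 = model$perm$p_value)
  }
  pj <- file.path(dir, "model.json")
  jsonlite::write_json(meta, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mats <- list(weights_b1 = model$weights_b1, weights_b2 = model$weights_b2,
               scores_b1 = model$scores_b1, scores_b2 = model$scores_b2,
               corr_loadings_b1 = model$corr_loadings_b1,
               corr_loadings_b2 = model$corr_loadings_b2,
               sig_mask_b1 = model$sig_mask_b1,
               sig_mask_b2 = model$sig_mask_b2)
  paths <- vapply(names(mats), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    id_col <- if (grepl("^scores", nm)) "trial_id" else "variable"
    write_matrix_tsv(mats[[nm]], p, id_col = id_col)
    p
  }, character(1))
  ps <- file.path(dir, "scree.tsv")
  write_tsv(scree_table(model), ps)
  invisible(c(pj, paths, ps))
}
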