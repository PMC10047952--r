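#' Principal-component endophenotypes from a feature matrix
#'
#' Reduces the subjects x 100 feature matrix to the top principal
#' components (default 10) used as endophenotypes: columns are
#' mean-centered (no variance scaling by default), components are the
#' leading eigenvectors of the sample covariance, and scores are the
#' centered features projected onto them. For a reproducible sign
#' convention, each loading column is flipped so its largest-magnitude
#' element is positive. If the feature matrix has rank below
#' `n_components`, fewer components are returned with a warning.
#'
#' @param features numeric matrix, subjects x features.
#' @param n_components number of PCs to keep (default 10).
#' @param scale. also scale columns to unit variance (default FALSE).
#' @return object of class `endophenotypes`: `scores` (subjects x k,
#'   columns `PC1..PCk`), `loadings` (features x k, orthonormal columns),
#'   `explained_variance_ratio` (fractions of total variance,
#'   non-increasing), `center`, and `scale`.
#' @export
fit_pca <- function(features, n_components = 10, scale. = FALSE) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stopf("features must be finite")
  if (nrow(features) <= n_components) {
    stopf("need more subjects (%d) than components (%d)",
          nrow(features), n_components,
          class = "deepgwas_parameter_error")
  }
  pr <- prcomp(features, center = TRUE, scale. = scale.)
  tot <- sum(pr$sdev^2)
  rank <- sum(pr$sdev > max(pr$sdev[1], 1e-300) * 1e-9)
  k <- min(n_components, rank)
  if (k < n_components) {
    warning(sprintf("feature rank %d < %d components requested; returning %d",
                    rank, n_components, k))
  }
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = pr$sdev[seq_len(k)]^2 / tot,
         center = pr$center,
         scale = if (isTRUE(scale.)) pr$scale else NULL),
    class = "endophenotypes")
}

#' @export
print.endophenotypes <- function(x, ...) {
  cat(sprintf("endophenotypes: %d subjects x %d PCs (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Write / read endophenotype scores as TSV
#'
#' The phenotype file consumed by the association scan: `subject_id`
#' followed by one column per PC.
#'
#' @param endo an [fit_pca()] result.
#' @param subject_ids subject identifiers aligned with the score rows.
#' @param path output TSV path.
#' @export
write_endophenotypes <- function(endo, subject_ids, path) {
  df <- data.frame(subject_id = subject_ids, endo$scores,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endophenotypes
#' @param path TSV written by `write_endophenotypes`.
#' @return for the reader, a data.frame with `subject_id` and PC columns.
#' @export
read_endophenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Interpretation regressions of PCs on ROI volumes
#'
#' For every (PC, ROI) pair, fits the simple linear regression of the PC
#' score on the ROI volume (optionally adjusted for covariates) and
#' reports the slope, its standard error, and the two-sided t-test
#' p-value with `-log10(p)`. For simple regression the slope p-value is
#' direction-symmetric, so regressing PC on ROI versus ROI on PC is a
#' cosmetic choice. Constant ROI columns are skipped with a warning.
#'
#' @param endo an [fit_pca()] result.
#' @param roi_table data.frame with `subject_id` then one column per ROI,
#'   rows aligned with the endophenotype scores.
#' @param covariates optional data.frame of adjustment covariates.
#' @return data.frame with one row per (ROI, PC) pair: `roi_id`,
#'   `pc_index`, `slope`, `se`, `p_value`, `neg_log10_p`.
#' @export
roi_associations <- function(endo, roi_table, covariates = NULL) {
  scores <- endo$scores
  rois <- roi_table[, setdiff(names(roi_table), "subject_id"),
                    drop = FALSE]
  stopifnot(nrow(rois) == nrow(scores))
  out <- list()
  for (roi in names(rois)) {
    v <- rois[[roi]]
    if (stats::sd(v) == 0) {
      warning(sprintf("ROI %s is constant; skipped", roi))
      next
    }
    for (pc in seq_len(ncol(scores))) {
      dat <- data.frame(y = scores[, pc], roi = v)
      if (!is.null(covariates)) dat <- cbind(dat, covariates)
      fit <- lm(y ~ ., data = dat)
      sm <- summary(fit)$coefficients
      out[[length(out) + 1]] <- data.frame(
        roi_id = roi, pc_index = pc,
        slope = sm["roi", 1], se = sm["roi", 2],
        p_value = sm["roi", 4],
        neg_log10_p = -log10(sm["roi", 4]))
    }
  }
  do.call(rbind, out)
}
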