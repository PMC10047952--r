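#' Per-SNP linear-regression association scan for one endophenotype
#'
#' For every SNP, fits ordinary least squares of the phenotype on
#' `[intercept, dosage, covariates]` and reports the dosage coefficient,
#' its standard error, the Wald t statistic and the two-sided p-value.
#' Computation residualizes phenotype and dosages on the covariate
#' design once (Frisch-Waugh-Lovell), which is algebraically identical
#' to the full per-SNP regression. SNPs with observed MAF below
#' `maf_min` are excluded and recorded; missing dosages are mean-imputed
#' per SNP by default (keeping n constant) or dropped per SNP with
#' `missing = "complete"`. Results are ordered by (chromosome, position).
#' Genome-wide (5e-8) and suggestive (5e-6) significance flags and the
#' genomic inflation factor of the scan are attached.
#'
#' @param phenotype numeric vector (one PC score per subject).
#' @param genotypes a `genotype_matrix`.
#' @param covariates optional data.frame (e.g. age, sex, education,
#'   handedness); an intercept is always included.
#' @param maf_min observed-MAF exclusion threshold (default 0.01; set 0
#'   to disable).
#' @param missing `"impute"` (per-SNP mean imputation) or `"complete"`
#'   (per-SNP complete cases).
#' @return object of class `gwas_result`: `table` (snp_id, chrom, pos,
#'   a1, n_used, beta, se, t_stat, p_value, maf_observed, suggestive,
#'   genome_wide), `lambda_gc`, `skipped` (excluded SNPs with reasons),
#'   `n`, `df`.
#' @export
run_gwas <- function(phenotype, genotypes, covariates = NULL,
                     maf_min = 0.01, missing = c("impute", "complete")) {
  missing <- match.arg(missing)
  g <- genotypes
  G <- g$dosages
  storage.mode(G) <- "double"
  n <- length(phenotype)
  stopifnot(nrow(G) == n)

  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    X0 <- cbind(X0, as.matrix(covariates))
  }
  if (qr(X0)$rank < ncol(X0)) {
    stopf("covariate design is rank deficient",
          class = "deepgwas_parameter_error")
  }
  if (n <= ncol(X0) + 1) {
    stopf("need n > number of design columns + 1",
          class = "deepgwas_parameter_error")
  }

  has_na <- anyNA(G)
  if (has_na && missing == "impute") {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
    has_na <- FALSE
  }

  p_obs <- colMeans(G, na.rm = TRUE) / 2
  maf_obs <- pmin(p_obs, 1 - p_obs)
  keep <- maf_obs >= maf_min & !is.na(maf_obs)
  skipped <- data.frame(snp_id = g$snp_ids[!keep],
                        reason = rep("maf_below_min", sum(!keep)))
  if (!any(keep)) {
    stopf("all SNPs excluded by the MAF filter",
          class = "deepgwas_scan_error")
  }

  idx <- which(keep)
  df <- n - ncol(X0) - 1L
  qr0 <- qr(X0)
  beta <- se <- tstat <- pval <- rep(NA_real_, length(idx))
  n_used <- rep(n, length(idx))

  if (!has_na) {
    ry <- qr.resid(qr0, phenotype)
    RG <- qr.resid(qr0, G[, idx, drop = FALSE])
    gss <- colSums(RG^2)
    ok <- gss > 1e-12
    num <- colSums(RG * ry)
    beta[ok] <- num[ok] / gss[ok]
    rss <- sum(ry^2) - beta^2 * gss
    se[ok] <- sqrt(pmax(rss[ok], 0) / df / gss[ok])
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df)
    if (any(!ok)) {
      skipped <- rbind(skipped,
                       data.frame(snp_id = g$snp_ids[idx[!ok]],
                                  reason = "constant_after_adjustment"))
    }
    sub <- ok
  } else {
    # complete cases per SNP
    sub <- logical(length(idx))
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      cc <- !is.na(G[, j])
      nj <- sum(cc)
      dfj <- nj - ncol(X0) - 1L
      if (dfj < 1) next
      X <- cbind(X0[cc, , drop = FALSE], G[cc, j])
      fit <- stats::lm.fit(X, phenotype[cc])
      if (fit$rank < ncol(X)) next
      rssj <- sum(fit$residuals^2)
      XtXinv <- chol2inv(chol(crossprod(X)))
      bj <- fit$coefficients[ncol(X)]
      sej <- sqrt(rssj / dfj * XtXinv[ncol(X), ncol(X)])
      beta[jj] <- bj
      se[jj] <- sej
      tstat[jj] <- bj / sej
      pval[jj] <- 2 * pt(-abs(tstat[jj]), dfj)
      n_used[jj] <- nj
      sub[jj] <- TRUE
    }
    if (any(!sub)) {
      skipped <- rbind(skipped,
                       data.frame(snp_id = g$snp_ids[idx[!sub]],
                                  reason = "degenerate_design"))
    }
  }

  tab <- data.frame(
    snp_id = g$snp_ids[idx], chrom = g$chrom[idx], pos = g$pos[idx],
    a1 = g$a1[idx], n_used = n_used, beta = beta, se = se,
    t_stat = tstat, p_value = pval, maf_observed = maf_obs[idx])
  tab <- tab[sub & !is.na(tab$p_value), , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  # p-values live in (0, 1]: bound numerically-zero results at the
  # smallest representable double
  tab$p_value <- pmax(tab$p_value, 5e-324)
  tab$suggestive <- tab$p_value <= 5e-6
  tab$genome_wide <- tab$p_value <= 5e-8

  structure(
    list(table = tab, lambda_gc = genomic_lambda(tab$p_value),
         skipped = skipped, n = n, df = df),
    class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf(
    "gwas_result: %d SNPs tested (n=%d), lambda=%.3f, %d suggestive, %d genome-wide\n",
    nrow(x$table), x$n, x$lambda_gc, sum(x$table$suggestive),
    sum(x$table$genome_wide)))
  invisible(x)
}

#' Association scans for every PC endophenotype
#'
#' Runs [run_gwas()] once per PC column, mirroring the per-endophenotype
#' reporting convention: results are reported per PC with no cross-PC
#' multiple-testing correction (a documented property of the analysis,
#' not an oversight).
#'
#' @param endo an [fit_pca()] result (or a numeric score matrix).
#' @param genotypes a `genotype_matrix`.
#' @param covariates,maf_min,missing see [run_gwas()].
#' @return list of class `gwas_scan`: `results` (one `gwas_result` per
#'   PC) and `lambda_gc` (named per-PC inflation factors).
#' @export
gwas_scan <- function(endo, genotypes, covariates = NULL,
                      maf_min = 0.01, missing = "impute") {
  scores <- if (inherits(endo, "endophenotypes")) endo$scores else
    as.matrix(endo)
  results <- lapply(seq_len(ncol(scores)), function(j) {
    run_gwas(scores[, j], genotypes, covariates = covariates,
             maf_min = maf_min, missing = missing)
  })
  names(results) <- colnames(scores) %||% paste0("PC", seq_len(ncol(scores)))
  structure(
    list(results = results,
         lambda_gc = vapply(results, `[[`, numeric(1), "lambda_gc")),
    class = "gwas_scan")
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square quantiles implied by the p-values,
#' divided by the null 1-df chi-square median (0.4549364); a value near 1
#' indicates calibrated association statistics.
#'
#' @param p_values p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) {
    stopf("no p-values supplied", class = "deepgwas_parameter_error")
  }
  if (any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]",
          class = "deepgwas_parameter_error")
  }
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Plot-ready Manhattan table
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end) and
#' `-log10(p)`; the conventional genome-wide (5e-8) and suggestive
#' (5e-6) thresholds are attached as attributes.
#'
#' @param result a [run_gwas()] result.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `cum_pos`,
#'   `neg_log10_p`; attributes `genome_wide` and `suggestive` hold the
#'   threshold lines on the `-log10` scale.
#' @export
manhattan_table <- function(result) {
  tab <- result$table
  chroms <- sort(unique(tab$chrom))
  offset <- setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offset[as.character(ch)] <- run
    run <- run + max(tab$pos[tab$chrom == ch]) + 1
  }
  out <- data.frame(
    snp_id = tab$snp_id, chrom = tab$chrom, pos = tab$pos,
    cum_pos = tab$pos + offset[as.character(tab$chrom)],
    neg_log10_p = -log10(tab$p_value))
  attr(out, "genome_wide") <- -log10(5e-8)
  attr(out, "suggestive") <- -log10(5e-6)
  out
}

#' Plot-ready quantile-quantile table
#'
#' Sorted observed versus expected `-log10` uniform quantiles, with the
#' 95% pointwise band from the beta distribution of uniform order
#' statistics.
#'
#' @param result a [run_gwas()] result, or a numeric vector of p-values.
#' @return data.frame with `expected`, `observed`, `lower`, `upper`
#'   (all on the `-log10` scale).
#' @export
qq_table <- function(result) {
  p <- if (inherits(result, "gwas_result")) result$table$p_value else
    as.numeric(result)
  p <- sort(p[!is.na(p)])
  n <- length(p)
  i <- seq_len(n)
  data.frame(
    expected = -log10((i - 0.5) / n),
    observed = -log10(p),
    lower = -log10(qbeta(0.975, i, n - i + 1)),
    upper = -log10(qbeta(0.025, i, n - i + 1)))
}

#' Write PLINK-dialect association summary statistics
#'
#' Tab-delimited file with header `CHR SNP BP A1 TEST NMISS BETA SE STAT
#' P` (the `.assoc.linear` additive-test dialect), one row per tested
#' SNP; excluded SNPs are not written (they are recorded in the result's
#' `skipped` table).
#'
#' @param result a [run_gwas()] result.
#' @param path output file path.
#' @export
write_summary_stats <- function(result, path) {
  tab <- result$table
  out <- data.frame(CHR = tab$chrom, SNP = tab$snp_id, BP = tab$pos,
                    A1 = tab$a1, TEST = "ADD", NMISS = tab$n_used,
                    BETA = tab$beta, SE = tab$se, STAT = tab$t_stat,
                    P = tab$p_value)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write summary statistics to %s", path,
                 class = "deepgwas_io_error")
  invisible(path)
}

#' @rdname write_summary_stats
#' @return for the reader, the summary-statistics data.frame.
#' @export
read_summary_stats <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
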