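make_geno <- function(dosages, maf = NULL) {
  n_snps <- ncol(dosages)
  structure(
    list(dosages = dosages, snp_ids = sprintf("rs%06d", seq_len(n_snps)),
         chrom = rep_len(1:22, n_snps),
         pos = seq_len(n_snps) * 1000L,
         maf = maf %||% (colMeans(dosages, na.rm = TRUE) / 2),
         a1 = rep("A", n_snps), a2 = rep("B", n_snps)),
    class = "genotype_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the six-subject worked example matches closed-form OLS to 1e-12", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c(0, 0, 1, 1, 2, 2)
  res <- run_gwas(y, make_geno(matrix(g, 6, 1)), maf_min = 0)
  # hand matrix algebra: X = [1, g]
  X <- cbind(1, g)
  bhat <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% bhat
  s2 <- sum(r^2) / (6 - 2)
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  tt <- bhat[2] / se
  pp <- 2 * pt(-abs(tt), 4)
  expect_equal(res$table$beta, bhat[2], tolerance = 1e-12)
  expect_equal(res$table$se, se, tolerance = 1e-12)
  expect_equal(res$table$t_stat, tt, tolerance = 1e-12)
  expect_equal(res$table$p_value, pp, tolerance = 1e-12)
  expect_identical(res$table$n_used, 6L)
})

test_that("near-noiseless linear truth recovers beta = 0.5 at genome-wide significance", {
  set.seed(51)
  g <- rbinom(100, 2, 0.3)
  y <- 0.5 * g + rnorm(100, sd = 1e-6)
  res <- run_gwas(y, make_geno(matrix(g, 100, 1)), maf_min = 0)
  expect_lt(abs(res$table$beta - 0.5), 1e-3)
  expect_lt(res$table$p_value, 5e-8)
  expect_true(res$table$genome_wide && res$table$suggestive)
})

test_that("scan matches an independent lm() oracle on 20 random covariate designs", {
  set.seed(52)
  worst <- 0
  for (r in 1:20) {
    n <- sample(30:80, 1)
    covs <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 14, 3),
                       handedness = rbinom(n, 1, 0.9))
    G <- matrix(rbinom(n * 5, 2, runif(5, 0.1, 0.5)), n, 5, byrow = TRUE)
    y <- rnorm(n) + 0.3 * covs$age / 10 + 0.2 * G[, 1]
    res <- run_gwas(y, make_geno(G), covariates = covs, maf_min = 0)
    for (j in seq_len(nrow(res$table))) {
      k <- match(res$table$snp_id[j], sprintf("rs%06d", 1:5))
      fit <- summary(lm(y ~ G[, k] + age + sex + education + handedness,
                        data = covs))$coefficients
      worst <- max(worst,
                   abs(res$table$beta[j] - fit[2, 1]),
                   abs(res$table$se[j] - fit[2, 2]),
                   abs(res$table$p_value[j] - fit[2, 4]))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("null scan has calibrated type-I error and lambda near 1", {
  set.seed(53)
  g <- simulate_genotypes(400, 2000, seed = 53)
  y <- rnorm(400)
  res <- run_gwas(y, g, maf_min = 0.01)
  frac <- mean(res$table$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.01)
  expect_gt(res$lambda_gc, 0.9)
  expect_lt(res$lambda_gc, 1.1)
  # results ordered by genomic position
  expect_false(is.unsorted(order(res$table$chrom, res$table$pos)))
  ord <- order(res$table$chrom, res$table$pos)
  expect_identical(ord, seq_along(ord))
})

test_that("MAF filter excludes and records rare SNPs", {
  set.seed(54)
  G <- cbind(rbinom(200, 2, 0.25), c(1, rep(0, 199)),
             rbinom(200, 2, 0.4))
  res <- run_gwas(rnorm(200), make_geno(G), maf_min = 0.01)
  expect_identical(nrow(res$table), 2L)
  expect_identical(res$skipped$snp_id, "rs000002")
  expect_identical(res$skipped$reason, "maf_below_min")
  expect_error(run_gwas(rnorm(200), make_geno(G), maf_min = 0.49),
               class = "deepgwas_scan_error")
})

test_that("missing dosages: mean imputation keeps n, complete-case drops it", {
  set.seed(55)
  G <- matrix(rbinom(300, 2, 0.3), 100, 3)
  G[1:10, 2] <- NA
  y <- rnorm(100)
  imp <- run_gwas(y, make_geno(G), maf_min = 0)
  expect_true(all(imp$table$n_used == 100L))
  cc <- run_gwas(y, make_geno(G), maf_min = 0, missing = "complete")
  expect_identical(sort(cc$table$n_used), c(90L, 100L, 100L))
  # complete-case estimate equals lm on the observed subset
  obs <- !is.na(G[, 2])
  fit <- summary(lm(y[obs] ~ G[obs, 2]))$coefficients
  row <- cc$table[cc$table$snp_id == "rs000002", ]
  expect_equal(row$beta, fit[2, 1], tolerance = 1e-10)
  expect_equal(row$p_value, fit[2, 4], tolerance = 1e-10)
})

test_that("covariate adjustment removes a planted age confound", {
  set.seed(56)
  n <- 500
  age <- rnorm(n, 75, 6)
  old <- age > 75
  p <- ifelse(old, 0.35, 0.15)
  G <- vapply(1:400, function(j) rbinom(n, 2, p), numeric(n))
  y <- 0.08 * (age - 75) + rnorm(n)
  covs <- data.frame(age = age)
  raw <- run_gwas(y, make_geno(G), maf_min = 0)
  adj <- run_gwas(y, make_geno(G), covariates = covs, maf_min = 0)
  expect_gt(raw$lambda_gc, 1.15)
  expect_gt(adj$lambda_gc, 0.9)
  expect_lt(adj$lambda_gc, 1.1)
})

test_that("genomic lambda is definitional", {
  expect_equal(genomic_lambda(rep(0.5, 7)), 1, tolerance = 1e-12)
  set.seed(57)
  expect_lt(abs(genomic_lambda(runif(10000)) - 1), 0.05)
  expect_error(genomic_lambda(numeric(0)),
               class = "deepgwas_parameter_error")
  expect_error(genomic_lambda(c(0.5, 0)),
               class = "deepgwas_parameter_error")
  expect_error(genomic_lambda(c(0.5, 1.2)),
               class = "deepgwas_parameter_error")
})

test_that("manhattan and qq tables are plot-ready and definitional", {
  set.seed(58)
  g <- simulate_genotypes(100, 200, seed = 58)
  res <- run_gwas(rnorm(100), g, maf_min = 0)
  mt <- manhattan_table(res)
  expect_equal(attr(mt, "genome_wide"), -log10(5e-8), tolerance = 1e-12)
  expect_equal(attr(mt, "suggestive"), -log10(5e-6), tolerance = 1e-12)
  expect_equal(mt$neg_log10_p, -log10(res$table$p_value),
               tolerance = 1e-12)
  # cumulative coordinate strictly increases along the scan order
  expect_false(is.unsorted(mt$cum_pos[order(mt$chrom, mt$pos)],
                           strictly = TRUE))
  expect_equal(-log10(5e-8), 7.30103, tolerance = 1e-5)

  qt <- qq_table(res)
  n <- nrow(qt)
  expect_equal(qt$expected, -log10((seq_len(n) - 0.5) / n),
               tolerance = 1e-12)
  expect_false(is.unsorted(rev(qt$observed)))
  # a calibrated null stays inside the 95% band almost everywhere
  set.seed(59)
  qt2 <- qq_table(runif(5000))
  inside <- mean(qt2$observed >= qt2$lower & qt2$observed <= qt2$upper)
  expect_gt(inside, 0.9)
})

test_that("summary statistics round-trip in the PLINK linear dialect", {
  set.seed(60)
  g <- simulate_genotypes(80, 50, seed = 60)
  g$dosages[5, 7] <- NA
  res <- run_gwas(rnorm(80), g, maf_min = 0.05)
  path <- withr::local_tempfile(fileext = ".assoc.linear")
  write_summary_stats(res, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header, c("CHR", "SNP", "BP", "A1", "TEST", "NMISS",
                             "BETA", "SE", "STAT", "P"))
  back <- read_summary_stats(path)
  expect_identical(back$SNP, res$table$snp_id)
  expect_identical(unique(back$TEST), "ADD")
  expect_equal(back$BETA, res$table$beta, tolerance = 1e-12)
  expect_equal(back$P, res$table$p_value, tolerance = 1e-12)
  # skipped SNPs are absent from the file but logged
  expect_false(any(res$skipped$snp_id %in% back$SNP))
})

test_that("per-PC scans report separate, uncorrected results", {
  set.seed(61)
  g <- simulate_genotypes(120, 100, seed = 61)
  scores <- matrix(rnorm(120 * 3), 120, 3,
                   dimnames = list(NULL, paste0("PC", 1:3)))
  scan <- gwas_scan(scores, g)
  expect_length(scan$results, 3)
  expect_named(scan$lambda_gc, paste0("PC", 1:3))
  expect_identical(nrow(scan$results$PC1$table),
                   nrow(scan$results$PC2$table))
})
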