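#' Deterministic ellipsoid brain phantom
#'
#' Builds the fixed analytic template every synthetic subject starts from:
#' concentric ellipsoids giving three intensity tiers emulating CSF (outer
#' shell), gray matter, and white matter (core), on an exactly-zero
#' background. Semi-axes are 46% of each grid extent.
#'
#' @param grid_shape integer length-3 vector of voxel extents.
#' @param tiers named intensities for the three tissue tiers.
#' @return 3D numeric array.
#' @export
brain_template <- function(grid_shape,
                           tiers = c(csf = 0.3, gm = 0.65, wm = 1.0)) {
  stopifnot(length(grid_shape) == 3)
  ctr <- (grid_shape + 1) / 2
  ax <- 0.46 * grid_shape
  x <- (seq_len(grid_shape[1]) - ctr[1]) / ax[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) / ax[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r <- sqrt(r2)
  vol <- array(0, grid_shape)
  vol[r <= 1] <- tiers[["csf"]]
  vol[r <= 0.85] <- tiers[["gm"]]
  vol[r <= 0.55] <- tiers[["wm"]]
  vol
}

default_truth_cfg <- function() {
  list(
    causal_snp_ids = NULL,
    causal_effects = NULL,
    n_causal = 0L,
    signal_patch_index = c(1L, 1L, 0L),
    class_effect = c(CN = 0, MCI = 1, AD = 2),
    noise_sd = 1,
    covariate_effects = c(age = 0.02, sex = 0.1,
                          education = 0, handedness = 0),
    atrophy_gain = 0.08,
    voxel_noise_sd = 0.04
  )
}

#' Simulate a full imaging-genetics cohort with planted signal
#'
#' Generates aligned diagnosis labels, covariates, Hardy-Weinberg
#' genotypes, and 3D phantom volumes for `n_subjects`. Each subject gets a
#' latent atrophy score
#' \deqn{a_i = \sum_k \beta_k \tilde g_{ik} + \mathrm{shift}(\mathrm{label}_i)
#'   + \gamma^\top c_i + \varepsilon_i,\quad
#'   \varepsilon_i \sim N(0, \sigma^2),}
#' where \eqn{\tilde g} is the standardized minor-allele dosage of the
#' planted causal SNPs. The subject's volume is the ellipsoid template
#' minus a smooth Gaussian attenuation blob, centered in one cell of the
#' overlapping 3x3x3 patch grid, whose amplitude grows linearly
#' (monotonically) with \eqn{a_i}; independent Gaussian voxel noise is
#' added inside the brain mask only, so background stays exactly zero.
#'
#' Default class priors match a 229:400:188 CN:MCI:AD cohort composition.
#'
#' @param n_subjects cohort size.
#' @param grid_shape volume extents, each at least 24 so the overlapping
#'   3x3x3 patch grid is well defined. Default 48 cubed.
#' @param genotype_cfg list passed to [simulate_genotypes()]:
#'   `n_snps`, `maf_low`, `maf_high`.
#' @param truth_cfg list overriding the planted-signal configuration:
#'   `causal_snp_ids` (or `n_causal` to pick them reproducibly),
#'   `causal_effects` (standardized effect sizes, default 0.4 each),
#'   `signal_patch_index` (0-based (i,j,k) cell of the patch grid),
#'   `class_effect` (named per-class atrophy shift), `noise_sd`,
#'   `covariate_effects`, `atrophy_gain` (intensity attenuation per unit
#'   atrophy score), `voxel_noise_sd`.
#' @param class_priors class sampling probabilities (CN, MCI, AD).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort`: subject_ids, labels (factor
#'   CN/MCI/AD), covariates (data.frame: age, sex, education, handedness),
#'   volumes (4D array, subject index last), genotypes
#'   ([simulate_genotypes()] output), truth (planted ground-truth record),
#'   grid_shape.
#' @export
simulate_cohort <- function(n_subjects,
                            grid_shape = c(48L, 48L, 48L),
                            genotype_cfg = list(n_snps = 100L),
                            truth_cfg = list(),
                            class_priors = c(CN = 229, MCI = 400, AD = 188) / 817,
                            seed = 1) {
  if (any(grid_shape < 24)) {
    stopf("each grid dimension must be >= 24 (got %s)",
          paste(grid_shape, collapse = "x"),
          class = "deepgwas_parameter_error")
  }
  cfg <- utils::modifyList(default_truth_cfg(), truth_cfg)
  class_priors <- class_priors / sum(class_priors)

  geno <- simulate_genotypes(
    n_subjects,
    n_snps = genotype_cfg$n_snps %||% 100L,
    maf_low = genotype_cfg$maf_low %||% 0.05,
    maf_high = genotype_cfg$maf_high %||% 0.5,
    seed = sub_seed(seed, 1))

  # resolve the causal set
  causal_ids <- cfg$causal_snp_ids
  if (is.null(causal_ids) && cfg$n_causal > 0) {
    causal_ids <- with_seed(sub_seed(seed, 2),
                            sample(geno$snp_ids, cfg$n_causal))
  }
  causal_ids <- causal_ids %||% character(0)
  if (!all(causal_ids %in% geno$snp_ids)) {
    stopf("truth_cfg references unknown SNP ids: %s",
          paste(setdiff(causal_ids, geno$snp_ids), collapse = ", "),
          class = "deepgwas_parameter_error")
  }
  effects <- cfg$causal_effects %||% rep(0.4, length(causal_ids))
  if (length(effects) != length(causal_ids)) {
    stopf("causal_effects length does not match causal_snp_ids",
          class = "deepgwas_parameter_error")
  }

  classes <- c("CN", "MCI", "AD")
  with_seed(sub_seed(seed, 3), {
    labels <- factor(sample(classes, n_subjects, replace = TRUE,
                            prob = class_priors), levels = classes)
    covariates <- data.frame(
      age = round(rnorm(n_subjects, 75, 6), 1),
      sex = rbinom(n_subjects, 1L, 0.47),
      education = pmin(pmax(round(rnorm(n_subjects, 16, 3)), 6L), 20L),
      handedness = rbinom(n_subjects, 1L, 0.9))

    # latent atrophy score
    a <- rnorm(n_subjects, 0, cfg$noise_sd)
  })
  a <- a + cfg$class_effect[as.character(labels)]
  ce <- cfg$covariate_effects
  a <- a +
    ce[["age"]] * (covariates$age - 75) +
    ce[["sex"]] * covariates$sex +
    ce[["education"]] * (covariates$education - 16) +
    ce[["handedness"]] * covariates$handedness
  if (length(causal_ids)) {
    for (j in seq_along(causal_ids)) {
      k <- match(causal_ids[j], geno$snp_ids)
      p <- geno$maf[k]
      gstd <- (geno$dosages[, k] - 2 * p) / sqrt(2 * p * (1 - p))
      a <- a + effects[j] * gstd
    }
  }

  template <- brain_template(grid_shape)
  mask <- template > 0
  grid <- make_patch_grid(grid_shape, parts = 3, window_frac = 0.5)
  cell <- grid_cell(grid, cfg$signal_patch_index)
  # The blob sits inside its cell but offset toward the side least shared
  # with neighboring overlapping windows, and is compact (sigma = w/8) so
  # patch-level localization is meaningful.
  off <- c(0.25, 0.5, 0.75)[pmin(pmax(cell$index, 0L), 2L) + 1L]
  blob <- gaussian_blob(grid_shape,
                        center = cell$start + off * cell$extent,
                        sigma = cell$extent / 8)
  blob <- blob * mask

  volumes <- array(0, c(grid_shape, n_subjects))
  nvox <- prod(grid_shape)
  with_seed(sub_seed(seed, 4), {
    for (i in seq_len(n_subjects)) {
      v <- template - cfg$atrophy_gain * a[i] * blob
      v <- v + rnorm(nvox, 0, cfg$voxel_noise_sd) * mask
      volumes[, , , i] <- v
    }
  })

  subject_ids <- sprintf("S%04d", seq_len(n_subjects))
  rownames(geno$dosages) <- subject_ids
  rownames(covariates) <- subject_ids

  truth <- structure(
    list(causal_snp_ids = causal_ids, causal_effects = effects,
         signal_patch_index = as.integer(cfg$signal_patch_index),
         class_effect = cfg$class_effect, noise_sd = cfg$noise_sd,
         covariate_effects = ce, atrophy_gain = cfg$atrophy_gain,
         voxel_noise_sd = cfg$voxel_noise_sd, atrophy_score = a),
    class = "synthetic_truth")

  structure(
    list(subject_ids = subject_ids, labels = labels,
         covariates = covariates, volumes = volumes, genotypes = geno,
         truth = truth, grid_shape = as.integer(grid_shape)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%s), volumes %s, %d SNPs\n",
              length(x$subject_ids),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " "),
              paste(x$grid_shape, collapse = "x"),
              ncol(x$genotypes$dosages)))
  invisible(x)
}

# Smooth separable Gaussian bump, peak value 1 at `center`.
gaussian_blob <- function(grid_shape, center, sigma) {
  gx <- exp(-((seq_len(grid_shape[1]) - center[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((seq_len(grid_shape[2]) - center[2])^2) / (2 * sigma[2]^2))
  gz <- exp(-((seq_len(grid_shape[3]) - center[3])^2) / (2 * sigma[3]^2))
  outer(outer(gx, gy), gz)
}

#' Synthetic region-of-interest volume table
#'
#' Image-derived ROI analogues for a synthetic cohort: the mean intensity
#' of each cell of the overlapping 3x3x3 patch grid, one column per cell.
#' The cell carrying the planted signal plays the role of an
#' atrophy-sensitive region (e.g. a hippocampus analogue) in
#' interpretation regressions.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame with `subject_id` and one `ROI_i_j_k` column per
#'   patch cell (0-based indices).
#' @export
synthetic_roi_table <- function(cohort) {
  grid <- make_patch_grid(cohort$grid_shape, parts = 3, window_frac = 0.5)
  n <- length(cohort$subject_ids)
  out <- data.frame(subject_id = cohort$subject_ids)
  for (spec in grid) {
    rx <- spec$start[1] + seq_len(spec$extent[1])
    ry <- spec$start[2] + seq_len(spec$extent[2])
    rz <- spec$start[3] + seq_len(spec$extent[3])
    vals <- apply(cohort$volumes[rx, ry, rz, , drop = FALSE], 4, mean)
    out[[sprintf("ROI_%d_%d_%d", spec$index[1], spec$index[2],
                 spec$index[3])]] <- vals
  }
  out
}
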