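#' Assemble a validated end-to-end run configuration
#'
#' Defaults reproduce the analysis' stated settings: 27-patch overlapping
#' grid with top-5 branch fusion, 100-wide feature layer, 10 PC
#' endophenotypes, 30% dropout on two layers, six rotation-augmentation
#' angles, and 80/10/10 splits with 10 repeats.
#'
#' @param n_subjects synthetic cohort size.
#' @param grid_shape volume extents (each >= 24).
#' @param n_snps number of simulated SNPs.
#' @param model_type `"whole"` (whole-brain CNN) or `"multibranch"`.
#' @param n_classes 2 (AD vs CN) or 3 (CN/MCI/AD).
#' @param truth_cfg planted-signal overrides, see [simulate_cohort()].
#' @param n_components PCs kept as endophenotypes.
#' @param parts,window_frac,top_k multi-branch grid settings.
#' @param augment rotation-augment training images.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param fine_tune update branch trunks during fusion.
#' @param maf_min GWAS MAF filter.
#' @param seed global seed.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(n_subjects = 200, grid_shape = c(32L, 32L, 32L),
                       n_snps = 500, model_type = c("whole", "multibranch"),
                       n_classes = 3, truth_cfg = list(),
                       n_components = 10, parts = 3, window_frac = 0.5,
                       top_k = 5, augment = FALSE, epochs = 4,
                       batch_size = 16, lr = 1e-3, fine_tune = TRUE,
                       maf_min = 0.01, seed = 1) {
  model_type <- match.arg(model_type)
  stopifnot(n_subjects >= 20, all(grid_shape >= 24), n_snps >= 10,
            n_components >= 1, top_k >= 1)
  structure(
    list(n_subjects = n_subjects, grid_shape = as.integer(grid_shape),
         n_snps = n_snps, model_type = model_type,
         n_classes = as.integer(n_classes), truth_cfg = truth_cfg,
         n_components = n_components, parts = parts,
         window_frac = window_frac, top_k = top_k, augment = augment,
         epochs = epochs, batch_size = batch_size, lr = lr,
         fine_tune = fine_tune, maf_min = maf_min, seed = seed),
    class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic imaging-genetics analysis
#'
#' Executes simulate -> (train whole-brain | multi-branch) -> feature
#' extraction -> PCA -> per-PC GWAS -> ROI interpretation regressions,
#' writing every stage's artifacts under `out_dir` together with a run
#' manifest recording the seed and a configuration hash. With
#' `resume = TRUE`, stages whose outputs already exist under the same
#' configuration hash are skipped; mixing artifacts from a different
#' configuration is refused.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param resume reuse existing stage outputs when the config hash
#'   matches.
#' @param verbose print stage progress.
#' @return the run manifest (named list, also written as
#'   `run_manifest.json`): artifact paths, per-PC lambda, the
#'   configuration hash and seed.
#' @export
run_all <- function(config, out_dir, resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hash_path <- file.path(out_dir, "config_hash.txt")
  if (file.exists(hash_path)) {
    old <- readLines(hash_path, warn = FALSE)[1]
    if (!identical(old, hash)) {
      stopf("out_dir %s holds artifacts from a different configuration (%s != %s)",
            out_dir, old, hash, class = "deepgwas_config_error")
    }
  } else {
    writeLines(hash, hash_path)
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- simulate ------------------------------------------------------
  cohort_dir <- file.path(out_dir, "cohort")
  if (!(resume && file.exists(file.path(cohort_dir, "manifest.json")))) {
    say("stage simulate: %d subjects", config$n_subjects)
    cohort <- simulate_cohort(
      config$n_subjects, grid_shape = config$grid_shape,
      genotype_cfg = list(n_snps = config$n_snps),
      truth_cfg = config$truth_cfg, seed = config$seed)
    write_dataset(cohort, cohort_dir)
  } else {
    say("stage simulate: resumed")
    cohort <- read_dataset(cohort_dir)
  }
  labels <- cohort$labels
  if (config$n_classes == 2) {
    keep <- labels %in% c("CN", "AD")
  } else {
    keep <- rep(TRUE, length(labels))
  }
  volumes <- cohort$volumes[, , , keep, drop = FALSE]
  labels <- droplevels(labels[keep])
  subject_ids <- cohort$subject_ids[keep]

  # --- train + extract features -------------------------------------
  feat_path <- file.path(out_dir, "features.tsv")
  if (!(resume && file.exists(feat_path))) {
    plan <- split_plan(n_repeats = 1, seed = sub_seed(config$seed, 11))
    sp <- split_dataset(labels, plan)[[1]]
    if (config$augment) {
      aug <- augment_training_set(volumes[, , , sp$train, drop = FALSE],
                                  labels[sp$train])
      x_tr <- aug$volumes; y_tr <- aug$labels
    } else {
      x_tr <- volumes[, , , sp$train, drop = FALSE]
      y_tr <- labels[sp$train]
    }
    if (config$model_type == "whole") {
      say("stage train: whole-brain CNN")
      cfg <- cnn_config(config$grid_shape, n_classes = nlevels(labels))
      model <- build_model(cfg, seed = sub_seed(config$seed, 12))
      model <- train_cnn(model, x_tr, y_tr,
                         x_val = volumes[, , , sp$val, drop = FALSE],
                         y_val = labels[sp$val],
                         epochs = config$epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = sub_seed(config$seed, 13))
      features <- extract_features(model, volumes)
    } else {
      say("stage train: multi-branch (%d^3 grid, top %d)",
          config$parts, config$top_k)
      grid <- make_patch_grid(config$grid_shape, parts = config$parts,
                              window_frac = config$window_frac)
      reports <- train_branches(volumes, labels, grid,
                                train = sp$train, val = sp$val,
                                n_classes = nlevels(labels),
                                epochs = config$epochs,
                                batch_size = config$batch_size,
                                lr = config$lr,
                                seed = sub_seed(config$seed, 14))
      sel <- select_top_k(reports, k = config$top_k)
      write.table(sel$ranking, file.path(out_dir, "branch_ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fused <- build_fused_model(sel, n_classes = nlevels(labels),
                                 fine_tune = config$fine_tune,
                                 seed = sub_seed(config$seed, 15))
      fused <- train_fused(fused, volumes, labels,
                           train = sp$train, val = sp$val,
                           epochs = config$epochs,
                           batch_size = config$batch_size,
                           lr = config$lr,
                           seed = sub_seed(config$seed, 16))
      features <- extract_features(fused, volumes)
    }
    write.table(data.frame(subject_id = subject_ids, features),
                feat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    say("stage train: resumed")
    fdf <- read.table(feat_path, header = TRUE, sep = "\t")
    features <- as.matrix(fdf[, -1])
  }

  # --- PCA endophenotypes -------------------------------------------
  endo_path <- file.path(out_dir, "endophenotypes.tsv")
  endo <- fit_pca(features, n_components = config$n_components)
  write_endophenotypes(endo, subject_ids, endo_path)

  # --- GWAS ----------------------------------------------------------
  gwas_dir <- file.path(out_dir, "gwas")
  dir.create(gwas_dir, showWarnings = FALSE)
  geno <- cohort$genotypes
  geno$dosages <- geno$dosages[keep, , drop = FALSE]
  covs <- cohort$covariates[keep, , drop = FALSE]
  scan <- gwas_scan(endo, geno, covariates = covs,
                    maf_min = config$maf_min)
  stat_paths <- character(0)
  for (pc in names(scan$results)) {
    path <- file.path(gwas_dir, paste0(pc, ".assoc.linear"))
    write_summary_stats(scan$results[[pc]], path)
    write.table(manhattan_table(scan$results[[pc]]),
                file.path(gwas_dir, paste0(pc, ".manhattan.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qq_table(scan$results[[pc]]),
                file.path(gwas_dir, paste0(pc, ".qq.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stat_paths <- c(stat_paths, path)
  }
  jsonlite::write_json(as.list(scan$lambda_gc),
                       file.path(gwas_dir, "lambda.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- ROI interpretation -------------------------------------------
  roi_path <- file.path(out_dir, "roi_associations.tsv")
  roi <- synthetic_roi_table(cohort)[keep, , drop = FALSE]
  assoc <- roi_associations(endo, roi)
  write.table(assoc, roi_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    config_hash = hash, seed = config$seed,
    cohort = cohort_dir, features = feat_path,
    endophenotypes = endo_path, summary_stats = stat_paths,
    lambda_gc = as.list(scan$lambda_gc), roi_associations = roi_path)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
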