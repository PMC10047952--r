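#' Write a synthetic cohort to disk in standard interchange formats
#'
#' Volumes go out as NIfTI-1 (`.nii.gz`, one per subject), genotypes as
#' PLINK `.raw`-style additive-dosage text (columns FID IID PAT MAT SEX
#' PHENOTYPE then one `<snp>_<minor allele>` column per SNP; missing
#' dosages as NA) plus a `.map`-style file (chrom, id, 0, pos), covariates
#' and labels as TSV, and the planted ground truth as JSON. A JSON
#' manifest listing every artifact is written last and returned.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest as a named list (also written to
#'   `manifest.json`).
#' @export
write_dataset <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stopf("cannot create output directory: %s", out_dir,
          class = "deepgwas_io_error")
  }
  n <- length(cohort$subject_ids)

  vol_paths <- file.path("volumes",
                         paste0(cohort$subject_ids, ".nii.gz"))
  for (i in seq_len(n)) {
    RNifti::writeNifti(cohort$volumes[, , , i],
                       file.path(out_dir, vol_paths[i]))
  }

  cov_path <- "covariates.tsv"
  cov <- cbind(subject_id = cohort$subject_ids,
               label = as.character(cohort$labels),
               cohort$covariates)
  write.table(cov, file.path(out_dir, cov_path), sep = "\t",
              quote = FALSE, row.names = FALSE)

  g <- cohort$genotypes
  raw_path <- "genotypes.raw"
  raw <- data.frame(FID = cohort$subject_ids, IID = cohort$subject_ids,
                    PAT = 0L, MAT = 0L,
                    SEX = cohort$covariates$sex + 1L,
                    PHENOTYPE = -9L)
  dos <- as.data.frame(g$dosages)
  names(dos) <- paste0(g$snp_ids, "_", g$a1)
  raw <- cbind(raw, dos)
  write.table(raw, file.path(out_dir, raw_path), sep = " ",
              quote = FALSE, row.names = FALSE)

  map_path <- "genotypes.map"
  write.table(data.frame(g$chrom, g$snp_ids, 0L, g$pos),
              file.path(out_dir, map_path), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  truth_path <- NULL
  if (!is.null(cohort$truth)) {
    truth_path <- "truth.json"
    jsonlite::write_json(unclass(cohort$truth),
                         file.path(out_dir, truth_path),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    n_subjects = n, grid_shape = as.integer(cohort$grid_shape),
    subject_ids = cohort$subject_ids, volumes = vol_paths,
    covariates = cov_path, genotypes_raw = raw_path,
    genotypes_map = map_path, truth = truth_path,
    maf = g$maf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_dataset()]
#'
#' @param dir directory containing `manifest.json`.
#' @return A `cohort` object; volumes are re-read from NIfTI so voxel
#'   data agree with the originals to float precision.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stopf("no manifest.json under %s", dir, class = "deepgwas_io_error")
  }
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  shape <- as.integer(m$grid_shape)
  n <- m$n_subjects

  volumes <- array(0, c(shape, n))
  for (i in seq_len(n)) {
    volumes[, , , i] <- as.array(RNifti::readNifti(file.path(dir, m$volumes[i])))
  }

  cov <- read.table(file.path(dir, m$covariates), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  labels <- factor(cov$label, levels = c("CN", "MCI", "AD"))
  covariates <- cov[, c("age", "sex", "education", "handedness")]
  rownames(covariates) <- cov$subject_id

  raw <- read.table(file.path(dir, m$genotypes_raw), header = TRUE,
                    sep = " ", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
  snp_cols <- setdiff(names(raw),
                      c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  dos <- as.matrix(raw[, snp_cols, drop = FALSE])
  snp_ids <- sub("_[^_]+$", "", snp_cols)
  a1 <- sub("^.*_", "", snp_cols)
  map <- read.table(file.path(dir, m$genotypes_map), header = FALSE,
                    sep = "\t", stringsAsFactors = FALSE)
  names(map) <- c("chrom", "snp_id", "cm", "pos")
  ord <- match(snp_ids, map$snp_id)
  colnames(dos) <- snp_ids
  rownames(dos) <- raw$IID
  maf <- if (!is.null(m$maf)) as.numeric(m$maf) else
    unname(colMeans(dos, na.rm = TRUE) / 2)
  geno <- structure(
    list(dosages = dos, snp_ids = snp_ids, chrom = map$chrom[ord],
         pos = map$pos[ord], maf = maf, a1 = a1,
         a2 = rep("B", length(snp_ids))),
    class = "genotype_matrix")

  truth <- NULL
  if (!is.null(m$truth)) {
    truth <- jsonlite::read_json(file.path(dir, m$truth),
                                 simplifyVector = TRUE)
    class(truth) <- "synthetic_truth"
  }

  structure(
    list(subject_ids = cov$subject_id, labels = labels,
         covariates = covariates, volumes = volumes, genotypes = geno,
         truth = truth, grid_shape = shape),
    class = "cohort")
}
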