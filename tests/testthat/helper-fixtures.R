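# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small binary cohort with a strong localized class signal (default cell).
fixture_binary_cohort <- function() {
  if (is.null(.fixtures$binary)) {
    .fixtures$binary <- simulate_cohort(
      60, grid_shape = c(24, 24, 24),
      genotype_cfg = list(n_snps = 30),
      truth_cfg = list(class_effect = c(CN = 0, MCI = 0, AD = 3),
                       noise_sd = 1),
      class_priors = c(CN = 1, MCI = 0, AD = 1), seed = 101)
  }
  .fixtures$binary
}

# Tiny separable volume set built directly (no cohort machinery): class 2
# gets a bright off-center bump, far above the voxel noise.
fixture_separable_volumes <- function(n = 40, shape = c(9, 9, 9),
                                      shift = 1, seed = 11) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), length.out = n))
  x <- array(rnorm(prod(shape) * n, sd = 0.5), c(shape, n))
  bump <- array(0, shape)
  bump[3:5, 3:5, 3:5] <- shift
  for (i in which(y == "B")) x[, , , i] <- x[, , , i] + bump
  list(x = x, y = y)
}

expect_same_numeric <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
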