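test_that("the default grid yields 27 overlapping patches with the stated starts", {
  grid <- make_patch_grid(c(48, 48, 48))
  expect_length(grid, 27)
  # axis rule at L = 48, w = 24: starts 0, 12, 24
  starts_x <- unique(vapply(grid, function(g) g$start[1], numeric(1)))
  expect_identical(sort(starts_x), c(0, 12, 24))
  expect_true(all(vapply(grid, function(g) all(g$extent == 24),
                         logical(1))))
  # lexicographic (i, j, k) ordering
  idx <- t(vapply(grid, `[[`, integer(3), "index"))
  expect_identical(idx[1, ], c(0L, 0L, 0L))
  expect_identical(idx[2, ], c(0L, 0L, 1L))
  expect_identical(idx[27, ], c(2L, 2L, 2L))
  # adjacent windows overlap by 12 and unions cover the axis
  expect_identical(sort(starts_x + 24), c(24, 36, 48))
})

test_that("grid coverage: every voxel in >= 1 patch, corners in exactly 1, center in the middle patch", {
  shape <- c(32, 30, 28)
  grid <- make_patch_grid(shape)
  cover <- array(0L, shape)
  for (g in grid) {
    rx <- g$start[1] + seq_len(g$extent[1])
    ry <- g$start[2] + seq_len(g$extent[2])
    rz <- g$start[3] + seq_len(g$extent[3])
    cover[rx, ry, rz] <- cover[rx, ry, rz] + 1L
  }
  expect_true(all(cover >= 1L))
  expect_identical(cover[1, 1, 1], 1L)
  expect_identical(cover[shape[1], shape[2], shape[3]], 1L)
  ctr <- grid[[14]]  # (1,1,1)
  expect_true(all((ctr$start < shape / 2) & (ctr$start + ctr$extent > shape / 2)))
})

test_that("degenerate grids are rejected and parts = 1 centers a single window", {
  expect_error(make_patch_grid(c(12, 48, 48)),
               class = "deepgwas_config_error")
  expect_error(make_patch_grid(c(48, 48, 48), window_frac = 0.2),
               class = "deepgwas_config_error")
  g1 <- make_patch_grid(c(48, 48, 48), parts = 1)
  expect_length(g1, 1)
  expect_identical(g1[[1]]$start, c(12L, 12L, 12L))
})

test_that("top-k selection applies accuracy, AUC, then lexicographic tie-breaks", {
  fake_reports <- function(acc, auc) {
    grid <- make_patch_grid(c(48, 48, 48))[seq_along(acc)]
    tab <- do.call(rbind, lapply(seq_along(acc), function(b) {
      data.frame(branch = b, i = grid[[b]]$index[1],
                 j = grid[[b]]$index[2], k = grid[[b]]$index[3],
                 val_accuracy = acc[b], val_auc = auc[b],
                 converged = TRUE)
    }))
    structure(list(table = tab, models = as.list(seq_along(acc)),
                   grid = grid), class = "branch_reports")
  }
  # accuracy dominates; AUC breaks the 0.8 tie; order (1st, 2nd, 3rd)
  r <- fake_reports(c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5),
                    c(0.5, 0.85, 0.80, 0.9, 0.9, 0.9))
  sel <- select_top_k(r, 3)
  expect_identical(sel$table$branch, c(1L, 2L, 3L))
  # all equal: first k in lexicographic patch order
  r2 <- fake_reports(rep(0.7, 6), rep(0.7, 6))
  sel2 <- select_top_k(r2, 5)
  expect_identical(sel2$table$branch, 1:5)
  expect_length(sel2$patches, 5)
  # invariance to report ordering
  perm <- c(4, 1, 6, 2, 5, 3)
  r3 <- r
  r3$table <- r$table[perm, ]
  sel3 <- select_top_k(r3, 3)
  expect_identical(sort(sel3$table$branch), sort(sel$table$branch))
  expect_identical(sel3$table$val_accuracy, sel$table$val_accuracy)
  expect_error(select_top_k(r, 7), class = "deepgwas_parameter_error")
})

test_that("branch training reports are deterministic and flag the signal patch", {
  co <- fixture_binary_cohort()
  labels <- droplevels(co$labels)
  sp <- split_dataset(labels, split_plan(n_repeats = 1, seed = 44))[[1]]
  grid <- make_patch_grid(co$grid_shape)
  # signal cell (1,1,0) plus three distant patches
  use <- list(deepgwas:::grid_cell(grid, c(1, 1, 0)),
              deepgwas:::grid_cell(grid, c(2, 2, 2)),
              deepgwas:::grid_cell(grid, c(0, 2, 2)),
              deepgwas:::grid_cell(grid, c(2, 0, 2)))
  r <- train_branches(co$volumes, labels, use, sp$train, sp$val,
                      n_classes = 2, epochs = 4, batch_size = 12,
                      lr = 2e-3, seed = 4)
  expect_identical(nrow(r$table), 4L)
  expect_true(all(r$table$converged))
  expect_true(all(r$table$val_accuracy >= 0 & r$table$val_accuracy <= 1))
  # the signal-bearing patch dominates the distant ones
  expect_identical(which.max(r$table$val_auc), 1L)
  r2 <- train_branches(co$volumes, labels, use, sp$train, sp$val,
                       n_classes = 2, epochs = 4, batch_size = 12,
                       lr = 2e-3, seed = 4)
  expect_identical(r$table, r2$table)
})

test_that("fused model keeps the 100-wide feature contract over k patch inputs", {
  co <- fixture_binary_cohort()
  labels <- droplevels(co$labels)
  sp <- split_dataset(labels, split_plan(n_repeats = 1, seed = 44))[[1]]
  grid <- make_patch_grid(co$grid_shape)
  use <- list(deepgwas:::grid_cell(grid, c(1, 1, 0)),
              deepgwas:::grid_cell(grid, c(1, 1, 1)),
              deepgwas:::grid_cell(grid, c(0, 1, 1)),
              deepgwas:::grid_cell(grid, c(2, 1, 1)),
              deepgwas:::grid_cell(grid, c(1, 0, 1)))
  r <- train_branches(co$volumes, labels, use, sp$train, sp$val,
                      n_classes = 2, dense_widths = c(20),
                      epochs = 2, batch_size = 12, seed = 6)
  sel <- select_top_k(r, 5)
  fused <- build_fused_model(sel, n_classes = 2, fine_tune = FALSE,
                             seed = 6)
  expect_length(fused$trunks, 5)
  expect_identical(nrow(fused$joint[[1]]$W), 5L * 20L)
  expect_identical(ncol(fused$joint[[1]]$W), 100L)
  fused <- train_fused(fused, co$volumes, labels, sp$train, sp$val,
                       epochs = 3, batch_size = 12, seed = 6)
  feats <- extract_features(fused, co$volumes)
  expect_identical(dim(feats), c(60L, 100L))
  probs <- predict(fused, co$volumes)
  expect_equal(rowSums(probs), rep(1, 60), tolerance = 1e-12)
})

test_that("a single frozen branch's fused predictions track the branch's own", {
  co <- fixture_binary_cohort()
  labels <- droplevels(co$labels)
  sp <- split_dataset(labels, split_plan(n_repeats = 1, seed = 44))[[1]]
  grid <- make_patch_grid(co$grid_shape)
  use <- list(deepgwas:::grid_cell(grid, c(1, 1, 0)))
  r <- train_branches(co$volumes, labels, use, sp$train, sp$val,
                      n_classes = 2, epochs = 5, batch_size = 12,
                      lr = 2e-3, seed = 8)
  sel <- select_top_k(r, 1)
  fused <- build_fused_model(sel, n_classes = 2, fine_tune = FALSE,
                             seed = 8)
  fused <- train_fused(fused, co$volumes, labels, sp$train, sp$val,
                       epochs = 8, batch_size = 12, lr = 2e-3, seed = 8)
  pf <- predict(fused, co$volumes)[, 2]
  pb <- predict(sel$models[[1]],
                extract_patch(co$volumes, use[[1]]))[, 2]
  expect_gte(cor(pf, pb, method = "spearman"), 0.9)
})
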