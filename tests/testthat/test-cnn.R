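test_that("default architecture carries a 100-unit penultimate layer and two dropout layers", {
  cfg <- cnn_config(c(48, 48, 48), n_classes = 3)
  m <- build_model(cfg, seed = 1)
  feat_dense <- m$layers[[m$feature_index - 1]]
  expect_identical(feat_dense$type, "dense")
  expect_identical(ncol(feat_dense$W), 100L)
  drops <- Filter(function(l) l$type == "dropout", m$layers)
  expect_length(drops, 2)
  expect_true(all(vapply(drops, `[[`, numeric(1), "p") == 0.30))
  # default stack for 48^3 reaches 4 conv blocks
  expect_length(cfg$conv_blocks, 4)
})

test_that("layer shapes propagate as hand-computed and underflow errors name the block", {
  cfg <- cnn_config(c(16, 16, 16), n_classes = 2,
                    conv_blocks = list(c(4, 3, 2), c(8, 3, 2)),
                    dense_widths = c(100))
  m <- build_model(cfg, seed = 1)
  # 16 -conv3-> 14 -pool2-> 7 -conv3-> 5 -pool2-> 2 ; flatten 2^3 * 8 = 64
  flat_dense <- m$layers[[m$feature_index - 1]]
  expect_identical(nrow(flat_dense$W), 64L)
  bad <- cnn_config(c(16, 16, 16), n_classes = 2,
                    conv_blocks = list(c(4, 3, 2), c(8, 3, 2), c(8, 3, 2)))
  expect_error(build_model(bad), "block 3",
               class = "deepgwas_config_error")
})

test_that("softmax output normalizes and predictions are deterministic", {
  cfg <- cnn_config(c(9, 9, 9), n_classes = 3,
                    conv_blocks = list(c(3, 3, 2)), dense_widths = c(12))
  m <- build_model(cfg, seed = 2)
  x <- array(rnorm(9^3 * 3), c(9, 9, 9, 3))
  p <- predict(m, x)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_identical(p, predict(m, x))
})

test_that("feature extraction is pure: dropout off, identical rows for identical input", {
  fx <- fixture_separable_volumes(n = 16, seed = 4)
  cfg <- cnn_config(c(9, 9, 9), n_classes = 2,
                    conv_blocks = list(c(3, 3, 2)), dense_widths = c(100))
  m <- build_model(cfg, seed = 4)
  m <- train_cnn(m, fx$x, fx$y, epochs = 2, batch_size = 8, seed = 4)
  f1 <- extract_features(m, fx$x)
  f2 <- extract_features(m, fx$x)
  expect_identical(dim(f1), c(16L, 100L))
  expect_identical(f1, f2)  # dropout inactive at inference
  # duplicated input volume gives duplicated feature rows
  xdup <- fx$x[, , , c(1, 1, 5)]
  fd <- extract_features(m, xdup)
  expect_identical(fd[1, ], fd[2, ])
  expect_error(extract_features(m, array(0, c(8, 8, 8, 2))),
               class = "deepgwas_input_error")
})

test_that("a linear-softmax head reproduces the CNN's own decisions on extracted features", {
  fx <- fixture_separable_volumes(n = 20, seed = 6)
  cfg <- cnn_config(c(9, 9, 9), n_classes = 2,
                    conv_blocks = list(c(3, 3, 2)), dense_widths = c(30))
  m <- build_model(cfg, seed = 6)
  m <- train_cnn(m, fx$x, fx$y, epochs = 3, batch_size = 10, seed = 6)
  feats <- extract_features(m, fx$x)
  head_dense <- m$layers[[length(m$layers)]]
  logits <- feats %*% head_dense$W + rep(head_dense$b, each = nrow(feats))
  expect_identical(max.col(logits), unname(predict(m, fx$x, type = "class")))
})

test_that("AUC matches pairwise concordance enumeration and is rank-invariant", {
  # 4-point worked example: concordant pairs / all pos-neg pairs = 3/4
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(evaluate_auc(labels, scores), 0.75, tolerance = 1e-15)
  brute <- function(lab, sc) {
    pos <- which(lab == 1); neg <- which(lab == 0)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(8)
  for (r in 1:10) {
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(30), 1)  # force some ties
    expect_equal(evaluate_auc(lab, sc), brute(lab, sc), tolerance = 1e-12)
    # invariance under strictly monotone transformation
    expect_equal(evaluate_auc(lab, exp(3 * sc)), evaluate_auc(lab, sc),
                 tolerance = 1e-12)
  }
  expect_equal(evaluate_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_error(evaluate_auc(c(1, 1), c(0.5, 0.6)),
               class = "deepgwas_evaluation_error")
})

test_that("AUC agrees with pROC and macro one-vs-rest averages per-class AUCs", {
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- rbinom(200, 1, 0.4)
  sc <- rnorm(200) + lab
  expect_equal(evaluate_auc(lab, sc),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
               tolerance = 1e-12)
  # macro OVR: average of the three one-vs-rest AUCs
  lab3 <- factor(sample(c("CN", "MCI", "AD"), 150, replace = TRUE),
                 levels = c("CN", "MCI", "AD"))
  probs <- matrix(runif(450), 150, 3,
                  dimnames = list(NULL, c("CN", "MCI", "AD")))
  probs <- probs / rowSums(probs)
  manual <- mean(vapply(levels(lab3), function(cl) {
    deepgwas:::auc_rank(probs[, cl], lab3 == cl)
  }, numeric(1)))
  expect_equal(evaluate_auc(lab3, probs, "macro_ovr"), manual,
               tolerance = 1e-12)
})

test_that("splits are stratified, disjoint, exhaustive and sized 80/10/10", {
  labels <- factor(rep(c("CN", "MCI", "AD"), times = c(50, 30, 20)),
                   levels = c("CN", "MCI", "AD"))
  plan <- split_plan(n_repeats = 4, seed = 99)
  splits <- split_dataset(labels, plan)
  expect_length(splits, 4)
  for (sp in splits) {
    expect_identical(lengths(sp), c(train = 80L, val = 10L, test = 10L))
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_identical(sort(all_idx), 1:100)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    # class proportions preserved within one subject
    for (part in sp) {
      tab <- table(labels[part])
      frac <- length(part) / 100
      expect_true(all(abs(tab - c(50, 30, 20) * frac) <= 1))
    }
  }
  # deterministic under the plan seed, varying across repeats
  splits2 <- split_dataset(labels, plan)
  expect_identical(splits, splits2)
  expect_false(identical(splits[[1]], splits[[2]]))
  expect_error(split_dataset(factor(rep(c("A", "B"), c(98, 2)))),
               class = "deepgwas_stratification_error")
})

test_that("training separates a separable binary set and is reproducible", {
  fx <- fixture_separable_volumes(n = 40, shift = 1.5, seed = 21)
  cfg <- cnn_config(c(9, 9, 9), n_classes = 2,
                    conv_blocks = list(c(4, 3, 2)), dense_widths = c(30))
  m <- build_model(cfg, seed = 5)
  sp <- split_dataset(fx$y, split_plan(n_repeats = 1, seed = 5))[[1]]
  m <- train_cnn(m, fx$x[, , , sp$train], fx$y[sp$train],
                 x_val = fx$x[, , , sp$val], y_val = fx$y[sp$val],
                 epochs = 12, batch_size = 16, seed = 5)
  expect_gte(max(m$history$val_auc), 0.95)
  # identical seeds reproduce the training history bit-for-bit
  m2 <- build_model(cfg, seed = 5)
  m2 <- train_cnn(m2, fx$x[, , , sp$train], fx$y[sp$train],
                  x_val = fx$x[, , , sp$val], y_val = fx$y[sp$val],
                  epochs = 12, batch_size = 16, seed = 5)
  expect_identical(m$history, m2$history)
})

test_that("shuffled labels yield chance-level test AUC", {
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    x <- array(rnorm(9^3 * 60), c(9, 9, 9, 60))
    y <- factor(rep(c("A", "B"), 30))
    cfg <- cnn_config(c(9, 9, 9), n_classes = 2,
                      conv_blocks = list(c(3, 3, 2)), dense_widths = c(10))
    m <- build_model(cfg, seed = s)
    m <- train_cnn(m, x[, , , 1:40], y[1:40], epochs = 3,
                   batch_size = 20, seed = s)
    deepgwas:::model_auc(predict(m, x[, , , 41:60]), y[41:60])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("rotation augmentation enlarges the training set seven-fold", {
  fx <- fixture_separable_volumes(n = 4, seed = 31)
  aug <- augment_training_set(fx$x, fx$y)
  expect_identical(dim(aug$volumes)[4], 28L)
  expect_length(aug$labels, 28)
  expect_identical(aug$volumes[, , , 1], fx$x[, , , 1])
  expect_identical(aug$labels[1:4], fx$y[1:4])
})
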