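#' Configuration for the 3D CNN classifier
#'
#' Describes the whole-brain (or per-patch) architecture: repeated
#' `[3D convolution -> ReLU -> 3D max-pool -> batch normalization]`
#' blocks, a flatten, a dense stack with exactly two dropout layers, a
#' 100-unit penultimate ("feature") dense layer, and a softmax head.
#' With the default four convolution blocks the network counts 14 layers
#' (4 conv + 4 pool + 4 batch-norm + feature dense + classifier head);
#' the count is configuration, not code.
#'
#' @param input_shape integer length-3 voxel extents of the input.
#' @param n_classes 2 or 3 output classes.
#' @param conv_blocks list of `c(channels, kernel, pool)` triples; `NULL`
#'   picks a stack automatically (kernel 3, pool 2, channels
#'   8, 16, 32, 64) as deep as the input shape allows, up to 4 blocks.
#' @param dense_widths widths of the dense stack; the last entry is the
#'   feature width (default 100) whose activations are extracted as
#'   image-derived features.
#' @param dropout_p dropout probability for the two dropout layers
#'   (default 0.30).
#' @param l2_lambda L2 weight-decay coefficient.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape, n_classes = 3, conv_blocks = NULL,
                       dense_widths = c(100), dropout_p = 0.30,
                       l2_lambda = 1e-4) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, n_classes >= 2)
  if (is.null(conv_blocks)) {
    conv_blocks <- list()
    s <- input_shape
    ch <- 8L
    while (length(conv_blocks) < 4 && all(s >= 3)) {
      conv_blocks[[length(conv_blocks) + 1]] <- c(min(ch, 64L), 3L, 2L)
      s <- (s - 2L) %/% 2L
      ch <- ch * 2L
    }
    if (!length(conv_blocks)) {
      stopf("input_shape too small for any convolution block",
            class = "deepgwas_config_error")
    }
  }
  structure(
    list(input_shape = input_shape, n_classes = as.integer(n_classes),
         conv_blocks = conv_blocks, dense_widths = dense_widths,
         dropout_p = dropout_p, l2_lambda = l2_lambda),
    class = "cnn_config")
}

#' Build an untrained 3D CNN from a configuration
#'
#' Validates that the input shape survives every convolution (valid, no
#' padding) and pooling step, initializes weights (He), and returns the
#' model handle. The penultimate dense layer carries the configured
#' feature width (100 by default); exactly two dropout layers flank it.
#'
#' @param config a [cnn_config()].
#' @param seed seed for weight initialization.
#' @return object of class `cnn_model` with elements `config`, `layers`,
#'   `feature_index` (layer whose output is the feature vector) and
#'   `n_params`.
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  with_seed(seed, {
    layers <- list()
    s <- config$input_shape
    ch <- 1L
    for (b in seq_along(config$conv_blocks)) {
      spec <- config$conv_blocks[[b]]
      out_ch <- spec[1]; kernel <- spec[2]; pool <- spec[3]
      if (any(s < kernel)) {
        stopf("block %d: kernel %d does not fit input %s", b, kernel,
              paste(s, collapse = "x"), class = "deepgwas_config_error")
      }
      s <- s - kernel + 1L
      if (any(s %/% pool < 1)) {
        stopf("block %d: pooling underflows shape %s", b,
              paste(s, collapse = "x"), class = "deepgwas_config_error")
      }
      layers <- c(layers, list(layer_conv(ch, out_ch, kernel),
                               layer_relu(), layer_pool(pool),
                               layer_bnorm(out_ch)))
      s <- s %/% pool
      ch <- out_ch
    }
    layers <- c(layers, list(layer_flatten()))
    d <- prod(s) * ch
    widths <- config$dense_widths
    if (length(widths) > 1) {
      for (w in widths[-length(widths)]) {
        layers <- c(layers, list(layer_dense(d, w), layer_relu()))
        d <- w
      }
    }
    feat_w <- widths[length(widths)]
    layers <- c(layers, list(layer_dropout(config$dropout_p),
                             layer_dense(d, feat_w), layer_relu()))
    feature_index <- length(layers)
    layers <- c(layers, list(layer_dropout(config$dropout_p),
                             layer_dense(feat_w, config$n_classes)))
  })
  stopifnot(sum(vapply(layers, function(l) l$type == "dropout",
                       logical(1))) == 2L)
  structure(
    list(config = config, layers = layers, feature_index = feature_index,
         n_params = n_params(layers), trained = FALSE, history = NULL),
    class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "cnn_model: input %s, %d conv blocks, feature width %d, %d classes, %s parameters%s\n",
    paste(x$config$input_shape, collapse = "x"),
    length(x$config$conv_blocks),
    x$config$dense_widths[length(x$config$dense_widths)],
    x$config$n_classes, format(x$n_params, big.mark = ","),
    if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Coerce volumes (3D, 4D subject-last, or 5D) to (x,y,z,1,N).
as_input <- function(volumes) {
  d <- dim(volumes)
  if (length(d) == 3) {
    dim(volumes) <- c(d, 1L, 1L)
  } else if (length(d) == 4) {
    volumes <- array(volumes, c(d[1:3], 1L, d[4]))
  } else if (length(d) != 5) {
    stopf("volumes must be a 3-, 4- or 5-d array")
  }
  volumes
}

labels_to_idx <- function(labels) {
  if (is.factor(labels)) as.integer(droplevels(labels)) else
    as.integer(factor(labels))
}

#' Train a CNN by mini-batch Adam on cross-entropy with L2 weight decay
#'
#' Runs mini-batch stochastic optimization, recording per-epoch training
#' loss and validation AUC (binary: positive-class probability; three or
#' more classes: macro one-vs-rest). The returned model carries the
#' weights of the epoch with the best validation AUC (when validation
#' data are given) and the full history.
#'
#' @param model a [build_model()] handle.
#' @param x training volumes (4D subject-last or 5D array).
#' @param y training labels (factor or integer).
#' @param x_val,y_val optional validation data for checkpoint selection.
#' @param epochs,batch_size,lr optimization hyperparameters.
#' @param seed seed controlling shuffling and dropout masks.
#' @param verbose print per-epoch progress.
#' @return the trained `cnn_model` with `history` (data.frame: epoch,
#'   loss, val_auc).
#' @export
train_cnn <- function(model, x, y, x_val = NULL, y_val = NULL,
                      epochs = 10, batch_size = 16, lr = 1e-3,
                      seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as_input(x)
  y_idx <- labels_to_idx(y)
  n <- dim(x)[5]
  stopifnot(length(y_idx) == n)
  layers <- model$layers
  opt <- adam_init(layers)
  l2 <- model$config$l2_lambda
  best_auc <- -Inf
  best_layers <- layers
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric())
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[, , , , idx, drop = FALSE]
        fw <- nn_forward(layers, xb, training = TRUE)
        layers <- fw$layers
        ce <- softmax_ce(fw$out, y_idx[idx])
        if (!is.finite(ce$loss)) {
          stopf("training diverged (non-finite loss) at epoch %d", ep,
                class = "deepgwas_training_error")
        }
        losses <- c(losses, ce$loss)
        bw <- nn_backward(layers, fw$caches, ce$dlogits)
        t <- t + 1L
        upd <- adam_step(layers, bw$grads, opt, lr, t, l2 = l2)
        layers <- upd$layers
        opt <- upd$opt
      }
      val_auc <- NA_real_
      if (!is.null(x_val)) {
        probs <- nn_predict_probs(layers, as_input(x_val))
        val_auc <- model_auc(probs, y_val)
        # ties prefer the later (more trained) epoch
        if (val_auc >= best_auc) {
          best_auc <- val_auc
          best_layers <- layers
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses),
                                  val_auc = val_auc))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f val_auc %.3f", ep,
                        mean(losses), val_auc))
      }
    }
  })
  model$layers <- if (!is.null(x_val)) best_layers else layers
  model$trained <- TRUE
  model$history <- history
  model
}

# Inference-mode class probabilities, batched to bound memory.
nn_predict_probs <- function(layers, x, batch = 64) {
  n <- dim(x)[5]
  out <- NULL
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    fw <- nn_forward(layers, x[, , , , idx, drop = FALSE],
                     training = FALSE)
    p <- softmax_probs(fw$out)
    out <- rbind(out, p)
  }
  out
}

#' Predict class probabilities or labels from a trained CNN
#'
#' @param object a trained `cnn_model`.
#' @param volumes input volumes (3D, 4D subject-last, or 5D).
#' @param type `"prob"` for the softmax matrix, `"class"` for argmax.
#' @param ... unused.
#' @export
predict.cnn_model <- function(object, volumes, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  p <- nn_predict_probs(object$layers, as_input(volumes))
  if (type == "prob") p else max.col(p)
}

#' Extract penultimate-layer features
#'
#' Returns the activations of the 100-unit penultimate dense layer
#' (post-ReLU) in inference mode: dropout off, batch normalization using
#' running statistics, hence deterministic for a fixed model.
#'
#' @param model a trained model (`cnn_model` or `fused_model`).
#' @param volumes input volumes aligned with the cohort.
#' @param ... passed to methods.
#' @return numeric matrix, subjects x feature width.
#' @export
extract_features <- function(model, volumes, ...) {
  UseMethod("extract_features")
}

#' @rdname extract_features
#' @export
extract_features.cnn_model <- function(model, volumes, ...) {
  x <- as_input(volumes)
  d_in <- dim(x)[1:3]
  if (!all(d_in == model$config$input_shape)) {
    stopf("input shape %s does not match model input %s",
          paste(d_in, collapse = "x"),
          paste(model$config$input_shape, collapse = "x"),
          class = "deepgwas_input_error")
  }
  n <- dim(x)[5]
  out <- NULL
  for (start in seq(1, n, by = 64)) {
    idx <- start:min(start + 63, n)
    fw <- nn_forward(model$layers, x[, , , , idx, drop = FALSE],
                     training = FALSE, tap = model$feature_index)
    out <- rbind(out, fw$tap)
  }
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; ties contribute 1/2. For more than two
#' classes the macro one-vs-rest average is used: each class's
#' probability column is scored against the indicator of that class and
#' the per-class AUCs are averaged.
#'
#' @param labels true labels (factor, character or 0/1). For binary
#'   scoring with a numeric `scores` vector the positive class is the
#'   second factor level (or 1).
#' @param scores numeric vector (binary) or subjects x classes
#'   probability matrix (`macro_ovr`).
#' @param scheme `"binary"` or `"macro_ovr"`.
#' @return scalar AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(labels, scores, scheme = c("binary", "macro_ovr")) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") {
    pos <- if (is.factor(labels)) {
      labels == levels(droplevels(labels))[2]
    } else as.logical(labels == max(labels))
    if (!any(pos) || all(pos)) {
      stopf("AUC undefined: only one class present",
            class = "deepgwas_evaluation_error")
    }
    auc_rank(scores, pos)
  } else {
    stopifnot(is.matrix(scores))
    f <- factor(labels)
    if (nlevels(droplevels(f)) < 2) {
      stopf("AUC undefined: only one class present",
            class = "deepgwas_evaluation_error")
    }
    present <- levels(droplevels(f))
    cols <- if (!is.null(colnames(scores))) {
      match(present, colnames(scores))
    } else match(present, levels(f))
    aucs <- vapply(seq_along(present), function(j) {
      auc_rank(scores[, cols[j]], f == present[j])
    }, numeric(1))
    mean(aucs)
  }
}

auc_rank <- function(scores, pos) {
  r <- rank(scores)
  np <- sum(pos)
  nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# AUC of a probability matrix against labels (binary -> positive-class
# column, else macro one-vs-rest).
model_auc <- function(probs, labels) {
  f <- factor(labels)
  if (nlevels(droplevels(f)) == 2 && ncol(probs) == 2) {
    evaluate_auc(droplevels(f), probs[, 2], "binary")
  } else {
    colnames(probs) <- levels(f)[seq_len(ncol(probs))]
    evaluate_auc(f, probs, "macro_ovr")
  }
}

#' Repeated stratified train/validation/test split plan
#'
#' @param fractions train/validation/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param n_repeats number of independent repeats (default 10).
#' @param seed seed making every repeat reproducible.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(fractions = c(0.8, 0.1, 0.1), n_repeats = 10,
                       seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  structure(list(fractions = fractions, n_repeats = n_repeats,
                 seed = seed), class = "split_plan")
}

#' Stratified index partitions for repeated splits
#'
#' Each repeat partitions `seq_along(labels)` into disjoint, exhaustive,
#' class-stratified train/validation/test sets with sizes rounding to the
#' plan fractions.
#'
#' @param labels class labels (factor or character).
#' @param plan a [split_plan()].
#' @return list of `n_repeats` lists with integer `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, plan = split_plan()) {
  f <- droplevels(factor(labels))
  n <- length(f)
  if (n < 10) stopf("need at least 10 subjects to split")
  if (any(table(f) < 3)) {
    stopf("every class needs at least 3 members for stratification",
          class = "deepgwas_stratification_error")
  }
  fr <- plan$fractions
  lapply(seq_len(plan$n_repeats), function(r) {
    with_seed(sub_seed(plan$seed, r), {
      train <- integer(0); val <- integer(0); test <- integer(0)
      for (cl in levels(f)) {
        idx <- sample(which(f == cl))
        m <- length(idx)
        n_test <- round(fr[3] * m)
        n_val <- round(fr[2] * m)
        test <- c(test, idx[seq_len(n_test)])
        val <- c(val, idx[n_test + seq_len(n_val)])
        train <- c(train, idx[-seq_len(n_test + n_val)])
      }
      list(train = sort(train), val = sort(val), test = sort(test))
    })
  })
}

#' Average test AUC over repeated splits
#'
#' Implements the repeated 80/10/10 evaluation protocol: per repeat,
#' train a fresh model on the training set (optionally with rotation
#' augmentation of training images only), select the best epoch on the
#' validation set, and score the held-out test set; the per-repeat test
#' AUCs are averaged.
#'
#' @param volumes 4D array (subject-last).
#' @param labels class labels.
#' @param config a [cnn_config()].
#' @param plan a [split_plan()].
#' @param augment apply the six-angle rotation augmentation to training
#'   images.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed base seed.
#' @return list with `test_auc` (per repeat), `mean_auc`, `val_auc`
#'   (best-epoch validation AUC per repeat).
#' @export
repeated_split_auc <- function(volumes, labels, config,
                               plan = split_plan(), augment = FALSE,
                               epochs = 8, batch_size = 16, lr = 1e-3,
                               seed = 1) {
  splits <- split_dataset(labels, plan)
  y <- droplevels(factor(labels))
  test_auc <- numeric(0)
  val_auc <- numeric(0)
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    x_tr <- volumes[, , , sp$train, drop = FALSE]
    y_tr <- y[sp$train]
    if (augment) {
      aug <- augment_training_set(x_tr, y_tr)
      x_tr <- aug$volumes
      y_tr <- aug$labels
    }
    model <- build_model(config, seed = sub_seed(seed, 100 + r))
    model <- train_cnn(model, x_tr, y_tr,
                       x_val = volumes[, , , sp$val, drop = FALSE],
                       y_val = y[sp$val],
                       epochs = epochs, batch_size = batch_size, lr = lr,
                       seed = sub_seed(seed, 200 + r))
    probs <- predict(model, volumes[, , , sp$test, drop = FALSE])
    test_auc <- c(test_auc, model_auc(probs, y[sp$test]))
    val_auc <- c(val_auc, max(model$history$val_auc, na.rm = TRUE))
  }
  list(test_auc = test_auc, mean_auc = mean(test_auc), val_auc = val_auc)
}

#' Rotation-augment a training set
#'
#' Appends the six default rotated copies of every training volume (the
#' originals come first), replicating labels accordingly.
#'
#' @param volumes 4D training array (subject-last).
#' @param labels training labels.
#' @param angles rotation angles in degrees.
#' @return list with `volumes` (4D) and `labels`.
#' @export
augment_training_set <- function(volumes, labels,
                                 angles = c(-20, -10, -5, 5, 10, 20)) {
  d <- dim(volumes)
  n <- d[4]
  k <- length(angles)
  out <- array(0, c(d[1:3], n * (k + 1)))
  out[, , , seq_len(n)] <- volumes
  for (i in seq_len(n)) {
    rots <- augment_rotations(volumes[, , , i], angles = angles)
    for (j in seq_len(k)) out[, , , n * j + i] <- rots[[j]]
  }
  list(volumes = out, labels = rep(labels, k + 1))
}

#' Baseline classifiers on extracted features
#'
#' Thin comparison utilities: L2-regularized logistic regression
#' (ridge via glmnet) and a linear SVM (e1071), fit on the feature matrix
#' with a train/test index split. Provided for parity with conventional
#' shallow classifiers on learned features.
#'
#' @param features subjects x features matrix.
#' @param labels binary labels (factor).
#' @param train,test integer index vectors.
#' @return named vector of test AUCs.
#' @export
baseline_classifiers <- function(features, labels, train, test) {
  y <- droplevels(factor(labels))
  stopifnot(nlevels(y) == 2)
  out <- c(logistic = NA_real_, svm = NA_real_)
  if (requireNamespace("glmnet", quietly = TRUE)) {
    fit <- glmnet::glmnet(features[train, ], y[train],
                          family = "binomial", alpha = 0, lambda = 0.05)
    sc <- as.numeric(stats::predict(fit, features[test, ],
                                    type = "response"))
    out["logistic"] <- evaluate_auc(y[test], sc, "binary")
  }
  if (requireNamespace("e1071", quietly = TRUE)) {
    fit <- e1071::svm(features[train, ], y[train], kernel = "linear",
                      probability = TRUE)
    pr <- attr(stats::predict(fit, features[test, ], probability = TRUE),
               "probabilities")
    out["svm"] <- evaluate_auc(y[test], pr[, levels(y)[2]], "binary")
  }
  out
}
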