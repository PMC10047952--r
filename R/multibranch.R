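#' Overlapping patch grid over a volume
#'
#' Divides each axis into `parts` overlapping windows of length
#' `round(window_frac * L)`; for the default three parts the window
#' starts are `0`, `floor((L - w)/2)` and `L - w` (generalized to evenly
#' spaced starts), giving the 27 overlapping patches of the 3x3x3 grid.
#' Windows on each axis overlap and their union covers it.
#'
#' @param shape integer length-3 volume extents.
#' @param parts windows per axis (default 3).
#' @param window_frac window length as a fraction of the axis (default
#'   0.5, i.e. 50% overlap between adjacent windows).
#' @return list of patch specs, ordered lexicographically by 0-based
#'   index `(i, j, k)`; each spec has `index`, `start` (0-based voxel
#'   offsets) and `extent`.
#' @export
make_patch_grid <- function(shape, parts = 3, window_frac = 0.5) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, parts >= 1)
  w <- as.integer(round(window_frac * shape))
  if (any(w < 8) || any(w >= shape)) {
    stopf("window %s degenerate for shape %s (need 8 <= w < L)",
          paste(w, collapse = "x"), paste(shape, collapse = "x"),
          class = "deepgwas_config_error")
  }
  starts_axis <- function(L, w) {
    if (parts == 1) return(as.integer((L - w) %/% 2))
    s <- as.integer(floor((seq_len(parts) - 1) * (L - w) / (parts - 1)))
    if (any(diff(s) >= w)) {
      stopf("windows do not overlap on an axis (w=%d, L=%d)", w, L,
            class = "deepgwas_config_error")
    }
    s
  }
  sx <- starts_axis(shape[1], w[1])
  sy <- starts_axis(shape[2], w[2])
  sz <- starts_axis(shape[3], w[3])
  grid <- list()
  for (i in seq_len(parts)) {
    for (j in seq_len(parts)) {
      for (k in seq_len(parts)) {
        grid[[length(grid) + 1]] <- list(
          index = c(i - 1L, j - 1L, k - 1L),
          start = c(sx[i], sy[j], sz[k]),
          extent = w)
      }
    }
  }
  grid
}

# Look up the grid cell with 0-based index triple `idx`.
grid_cell <- function(grid, idx) {
  for (spec in grid) {
    if (all(spec$index == as.integer(idx))) return(spec)
  }
  stopf("no grid cell with index (%s)", paste(idx, collapse = ","),
        class = "deepgwas_parameter_error")
}

#' Extract one patch from a volume or volume stack
#'
#' @param volumes 3D array or 4D array (subject-last).
#' @param spec a patch spec from [make_patch_grid()].
#' @return array of the patch extent (subject axis preserved).
#' @export
extract_patch <- function(volumes, spec) {
  rx <- spec$start[1] + seq_len(spec$extent[1])
  ry <- spec$start[2] + seq_len(spec$extent[2])
  rz <- spec$start[3] + seq_len(spec$extent[3])
  if (length(dim(volumes)) == 3) {
    volumes[rx, ry, rz, drop = FALSE]
  } else {
    volumes[rx, ry, rz, , drop = FALSE]
  }
}

#' Train one CNN per patch of the grid
#'
#' Trains a scaled-down CNN (input shape = patch extent) per patch on
#' identical train/validation splits across branches and reports each
#' branch's validation accuracy and AUC. A branch whose training
#' diverges is flagged (`converged = FALSE`) and the run continues.
#'
#' @param volumes 4D array (subject-last).
#' @param labels class labels.
#' @param grid patch list from [make_patch_grid()].
#' @param train,val integer index vectors shared by all branches.
#' @param n_classes number of classes.
#' @param conv_blocks,dense_widths,dropout_p,l2_lambda forwarded to
#'   [cnn_config()]; `conv_blocks = NULL` picks a stack automatically
#'   from the patch extent.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed base seed; identical seeds give identical reports.
#' @return object of class `branch_reports`: `table` (one row per patch,
#'   sorted by patch index), `models`, `grid`, and the split indices.
#' @export
train_branches <- function(volumes, labels, grid, train, val,
                           n_classes = 2, conv_blocks = NULL,
                           dense_widths = c(100),
                           dropout_p = 0.3, l2_lambda = 1e-4,
                           epochs = 4, batch_size = 16, lr = 2e-3,
                           seed = 1) {
  stopifnot(length(grid) >= 1)
  y <- droplevels(factor(labels))
  models <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (b in seq_along(grid)) {
    spec <- grid[[b]]
    xb <- extract_patch(volumes, spec)
    cfg <- cnn_config(spec$extent, n_classes = n_classes,
                      conv_blocks = conv_blocks,
                      dense_widths = dense_widths, dropout_p = dropout_p,
                      l2_lambda = l2_lambda)
    res <- tryCatch({
      model <- build_model(cfg, seed = sub_seed(seed, 1000 + b))
      model <- train_cnn(model, xb[, , , train, drop = FALSE], y[train],
                         x_val = xb[, , , val, drop = FALSE],
                         y_val = y[val],
                         epochs = epochs, batch_size = batch_size,
                         lr = lr, seed = sub_seed(seed, 2000 + b))
      probs <- predict(model, xb[, , , val, drop = FALSE])
      acc <- mean(max.col(probs) == as.integer(y[val]))
      list(model = model, acc = acc, auc = model_auc(probs, y[val]),
           converged = TRUE)
    }, deepgwas_training_error = function(e) {
      list(model = NULL, acc = NA_real_, auc = NA_real_,
           converged = FALSE)
    })
    models[[b]] <- res$model
    rows[[b]] <- data.frame(
      branch = b, i = spec$index[1], j = spec$index[2], k = spec$index[3],
      val_accuracy = res$acc, val_auc = res$auc, converged = res$converged)
  }
  structure(
    list(table = do.call(rbind, rows), models = models, grid = grid,
         train = train, val = val),
    class = "branch_reports")
}

#' Select the top-k branches by validation accuracy
#'
#' Ranks branches by validation accuracy, breaking ties by higher
#' validation AUC and then by lower lexicographic patch index, and keeps
#' the top `k` (the paper-default 5). Selection is invariant to the input
#' ordering of the reports; non-converged branches rank last.
#'
#' @param reports a [train_branches()] result.
#' @param k number of branches to retain (default 5).
#' @return object of class `branch_selection`: `patches`, `models`,
#'   `table` (the selected rows, best first), and the full ranking.
#' @export
select_top_k <- function(reports, k = 5) {
  tab <- reports$table
  if (k > nrow(tab)) {
    stopf("k = %d exceeds the %d available branches", k, nrow(tab),
          class = "deepgwas_parameter_error")
  }
  acc <- ifelse(is.na(tab$val_accuracy), -Inf, tab$val_accuracy)
  auc <- ifelse(is.na(tab$val_auc), -Inf, tab$val_auc)
  ord <- order(-acc, -auc, tab$i, tab$j, tab$k)
  sel <- ord[seq_len(k)]
  structure(
    list(patches = reports$grid[tab$branch[sel]],
         models = reports$models[tab$branch[sel]],
         table = tab[sel, ], ranking = tab[ord, ]),
    class = "branch_selection")
}

#' Build the fused multi-branch model
#'
#' Each selected branch contributes its convolutional trunk and dense
#' feature layer (initialized from per-branch training); per-branch
#' features are concatenated and passed through a joint 100-unit dense
#' feature layer and a softmax head, so the downstream feature contract
#' is identical to the whole-brain path. With `fine_tune = TRUE`
#' (default) all weights update during fusion training; otherwise the
#' trunks stay frozen and only the joint layers learn.
#'
#' @param selection a [select_top_k()] result.
#' @param n_classes output classes.
#' @param joint_width width of the fused feature layer (default 100).
#' @param fine_tune update branch trunks during fusion training.
#' @param seed seed for joint-layer initialization.
#' @return object of class `fused_model`.
#' @export
build_fused_model <- function(selection, n_classes = 2,
                              joint_width = 100, fine_tune = TRUE,
                              seed = 1) {
  stopifnot(length(selection$models) >= 1)
  trunks <- lapply(selection$models, function(m) {
    m$layers[seq_len(m$feature_index)]
  })
  widths <- vapply(selection$models, function(m) {
    w <- m$config$dense_widths
    as.integer(w[length(w)])
  }, integer(1))
  if (length(unique(widths)) != 1) {
    stopf("branch feature widths differ: %s",
          paste(widths, collapse = ", "),
          class = "deepgwas_config_error")
  }
  concat <- sum(widths)
  with_seed(seed, {
    joint <- list(layer_dense(concat, joint_width), layer_relu(),
                  layer_dense(joint_width, as.integer(n_classes)))
  })
  structure(
    list(patches = selection$patches, trunks = trunks,
         feature_widths = widths, joint = joint,
         joint_feature_index = 2L, n_classes = as.integer(n_classes),
         fine_tune = fine_tune, trained = FALSE, history = NULL),
    class = "fused_model")
}

# Forward through all trunks + joint stack; returns logits and caches.
fused_forward <- function(fm, volumes, training = FALSE) {
  feats <- vector("list", length(fm$trunks))
  trunk_caches <- vector("list", length(fm$trunks))
  trunks <- fm$trunks
  for (b in seq_along(trunks)) {
    xb <- as_input(extract_patch(volumes, fm$patches[[b]]))
    fw <- nn_forward(trunks[[b]], xb, training = training)
    trunks[[b]] <- fw$layers
    feats[[b]] <- fw$out
    trunk_caches[[b]] <- fw$caches
  }
  concat <- do.call(cbind, feats)
  jf <- nn_forward(fm$joint, concat, training = training)
  list(out = jf$out, joint_caches = jf$caches, trunk_caches = trunk_caches,
       trunks = trunks, joint = jf$layers, concat = concat)
}

#' Train the fused model
#'
#' Joint training of the fused architecture on cross-entropy. With
#' `fine_tune = FALSE` the branch features are precomputed once and only
#' the joint layers are optimized (fast); with `fine_tune = TRUE`
#' gradients flow into every branch trunk.
#'
#' @param fm a [build_fused_model()] handle.
#' @param volumes 4D array (subject-last), full volumes; patches are cut
#'   internally.
#' @param labels class labels.
#' @param train,val integer index vectors.
#' @param epochs,batch_size,lr optimization hyperparameters.
#' @param l2_lambda L2 penalty on dense/conv weights.
#' @param seed seed for shuffling and dropout.
#' @return the trained `fused_model` with `history`.
#' @export
train_fused <- function(fm, volumes, labels, train, val,
                        epochs = 6, batch_size = 16, lr = 1e-3,
                        l2_lambda = 1e-4, seed = 1) {
  y <- droplevels(factor(labels))
  y_idx <- as.integer(y)
  n_tr <- length(train)
  best_auc <- -Inf
  best <- list(trunks = fm$trunks, joint = fm$joint)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric())

  if (!fm$fine_tune) {
    feats_all <- fused_features_concat(fm, volumes)
    joint <- fm$joint
    opt <- adam_init(joint)
    t <- 0L
    with_seed(seed, {
      for (ep in seq_len(epochs)) {
        ord <- sample(train)
        losses <- numeric(0)
        for (s in seq(1, n_tr, by = batch_size)) {
          idx <- ord[s:min(s + batch_size - 1, n_tr)]
          fw <- nn_forward(joint, feats_all[idx, , drop = FALSE],
                           training = TRUE)
          joint <- fw$layers
          ce <- softmax_ce(fw$out, y_idx[idx])
          if (!is.finite(ce$loss)) {
            stopf("fused training diverged at epoch %d", ep,
                  class = "deepgwas_training_error")
          }
          losses <- c(losses, ce$loss)
          bw <- nn_backward(joint, fw$caches, ce$dlogits)
          t <- t + 1L
          upd <- adam_step(joint, bw$grads, opt, lr, t, l2 = l2_lambda)
          joint <- upd$layers
          opt <- upd$opt
        }
        fwv <- nn_forward(joint, feats_all[val, , drop = FALSE])
        va <- model_auc(softmax_probs(fwv$out), y[val])
        if (va >= best_auc) {
          best_auc <- va
          best <- list(trunks = fm$trunks, joint = joint)
        }
        history <- rbind(history, data.frame(epoch = ep,
                                             loss = mean(losses),
                                             val_auc = va))
      }
    })
  } else {
    trunks <- fm$trunks
    joint <- fm$joint
    opts <- lapply(trunks, adam_init)
    opt_j <- adam_init(joint)
    t <- 0L
    nb <- length(trunks)
    w <- fm$feature_widths
    col_hi <- cumsum(w)
    col_lo <- col_hi - w + 1
    with_seed(seed, {
      for (ep in seq_len(epochs)) {
        ord <- sample(train)
        losses <- numeric(0)
        for (s in seq(1, n_tr, by = batch_size)) {
          idx <- ord[s:min(s + batch_size - 1, n_tr)]
          xb <- volumes[, , , idx, drop = FALSE]
          fm$trunks <- trunks
          fm$joint <- joint
          fw <- fused_forward(fm, xb, training = TRUE)
          trunks <- fw$trunks
          joint <- fw$joint
          ce <- softmax_ce(fw$out, y_idx[idx])
          if (!is.finite(ce$loss)) {
            stopf("fused training diverged at epoch %d", ep,
                  class = "deepgwas_training_error")
          }
          losses <- c(losses, ce$loss)
          bj <- nn_backward(joint, fw$joint_caches, ce$dlogits)
          t <- t + 1L
          upd <- adam_step(joint, bj$grads, opt_j, lr, t, l2 = l2_lambda)
          joint <- upd$layers
          opt_j <- upd$opt
          for (b in seq_len(nb)) {
            dfeat <- bj$dx[, col_lo[b]:col_hi[b], drop = FALSE]
            bt <- nn_backward(trunks[[b]], fw$trunk_caches[[b]], dfeat)
            updb <- adam_step(trunks[[b]], bt$grads, opts[[b]], lr, t,
                              l2 = l2_lambda)
            trunks[[b]] <- updb$layers
            opts[[b]] <- updb$opt
          }
        }
        fm$trunks <- trunks
        fm$joint <- joint
        pv <- fused_predict_probs(fm, volumes[, , , val, drop = FALSE])
        va <- model_auc(pv, y[val])
        if (va >= best_auc) {
          best_auc <- va
          best <- list(trunks = trunks, joint = joint)
        }
        history <- rbind(history, data.frame(epoch = ep,
                                             loss = mean(losses),
                                             val_auc = va))
      }
    })
  }
  fm$trunks <- best$trunks
  fm$joint <- best$joint
  fm$trained <- TRUE
  fm$history <- history
  fm
}

# Concatenated frozen branch features for all subjects, inference mode.
fused_features_concat <- function(fm, volumes, batch = 64) {
  n <- dim(volumes)[4]
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    feats <- lapply(seq_along(fm$trunks), function(b) {
      xb <- as_input(extract_patch(volumes[, , , idx, drop = FALSE],
                                   fm$patches[[b]]))
      nn_forward(fm$trunks[[b]], xb)$out
    })
    out <- rbind(out, do.call(cbind, feats))
  }
  out
}

fused_predict_probs <- function(fm, volumes, batch = 64) {
  feats <- fused_features_concat(fm, volumes, batch = batch)
  softmax_probs(nn_forward(fm$joint, feats)$out)
}

#' @rdname extract_features
#' @export
extract_features.fused_model <- function(model, volumes, ...) {
  feats <- fused_features_concat(model, volumes)
  nn_forward(model$joint, feats, tap = model$joint_feature_index)$tap
}

#' Predict class probabilities from a fused model
#'
#' @param object a trained `fused_model`.
#' @param volumes 4D array (subject-last) of full volumes.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.fused_model <- function(object, volumes,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (length(dim(volumes)) == 3) dim(volumes) <- c(dim(volumes), 1L)
  p <- fused_predict_probs(object, volumes)
  if (type == "prob") p else max.col(p)
}

#' @export
print.fused_model <- function(x, ...) {
  cat(sprintf("fused_model: %d branches -> joint feature width %d, %d classes%s\n",
              length(x$trunks), ncol(x$joint[[1]]$W) %||% NA,
              x$n_classes, if (x$trained) " (trained)" else ""))
  invisible(x)
}
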