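#' Otsu threshold of a numeric vector
#'
#' Histogram-based threshold maximizing between-class variance; used by
#' [compute_brain_mask()] as the automatic foreground/background cut.
#'
#' @param x numeric values (finite).
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) {
    stopf("constant input: Otsu threshold undefined",
          class = "deepgwas_degenerate_error")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_m <- m[n_bins]
  total_w <- w[n_bins]
  # between-class variance for threshold after each bin
  w0 <- w[-n_bins]
  w1 <- total_w - w0
  ok <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (total_m - m[-n_bins]) / w1
  bcv <- ifelse(ok, w0 * w1 * (mu0 - mu1)^2, -Inf)
  breaks[which.max(bcv) + 1]
}

#' Brain mask surrogate for skull stripping
#'
#' Thresholds the volume (Otsu or fixed threshold) and keeps only the
#' largest 6-connected component, a stand-in for brain-extraction tools
#' when working with phantom or pre-stripped data. Real brain-extraction
#' masks can be supplied downstream instead.
#'
#' @param volume 3D numeric array.
#' @param method `"otsu"` (data-driven threshold) or `"fixed"`.
#' @param threshold cut for `method = "fixed"`; voxels strictly above it
#'   are foreground. Default 0.
#' @return logical array of the same shape.
#' @export
compute_brain_mask <- function(volume, method = c("otsu", "fixed"),
                               threshold = 0) {
  method <- match.arg(method)
  if (!all(is.finite(volume))) stopf("volume contains non-finite values")
  thr <- if (method == "otsu") otsu_threshold(as.vector(volume)) else threshold
  fg <- volume > thr
  if (!any(fg)) {
    stopf("empty mask: no voxels above threshold",
          class = "deepgwas_degenerate_error")
  }
  lab <- .label_components(fg)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  mask <- lab == keep
  dim(mask) <- dim(volume)
  mask
}

#' Crop a volume to the bounding box of a mask
#'
#' Returns the minimal axis-aligned bounding box of the mask, expanded by
#' `margin` voxels per side (clipped to the volume), with voxels outside
#' the mask set to zero — removing uninformative surrounding background.
#'
#' @param volume 3D numeric array.
#' @param mask logical array, same shape, nonempty.
#' @param margin nonnegative integer margin in voxels.
#' @return cropped 3D array with attribute `offset` (0-based corner of
#'   the crop in the original volume).
#' @export
crop_to_bbox <- function(volume, mask, margin = 0) {
  if (!any(mask)) {
    stopf("empty mask", class = "deepgwas_degenerate_error")
  }
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, dim(volume))
  out <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out[!m] <- 0
  attr(out, "offset") <- as.integer(lo - 1L)
  out
}

#' Gaussian-mixture tissue segmentation (FAST surrogate)
#'
#' Fits a 3-component univariate Gaussian mixture by EM to the in-mask
#' intensities and hard-assigns each voxel to the maximum-responsibility
#' component. Components ordered by mean map, ascending, to CSF < GM < WM
#' — the usual T1 intensity ordering. A reimplementation of the tissue
#' classification idea behind FSL FAST for dependency-free use; real
#' segmentations can be supplied as masks instead.
#'
#' @param volume 3D numeric array.
#' @param mask logical brain mask.
#' @param seed unused by the deterministic quantile initialization;
#'   retained for interface stability.
#' @param n_components number of tissue classes (3).
#' @param max_iter,tol EM stopping rule on relative log-likelihood change.
#' @return list of class `tissue_maps` with logical arrays `csf`, `gm`,
#'   `wm`, plus the fitted `means`, `sds`, `weights` and the
#'   `loglik_trace`.
#' @export
segment_tissues <- function(volume, mask, seed = 1, n_components = 3,
                            max_iter = 200, tol = 1e-8) {
  x <- volume[mask]
  if (length(unique(x)) < n_components) {
    stopf("need at least %d distinct in-mask intensities", n_components,
          class = "deepgwas_degenerate_error")
  }
  fit <- gmm1d_em(x, k = n_components, max_iter = max_iter, tol = tol)
  ord <- order(fit$means)
  post <- fit$post[, ord, drop = FALSE]
  assign <- max.col(post, ties.method = "first")

  in_mask <- which(mask)
  mk <- function(class_idx) {
    m <- array(FALSE, dim(volume))
    m[in_mask[assign == class_idx]] <- TRUE
    m
  }
  structure(
    list(csf = mk(1), gm = mk(2), wm = mk(3),
         means = fit$means[ord], sds = fit$sds[ord],
         weights = fit$weights[ord], loglik_trace = fit$loglik_trace),
    class = "tissue_maps")
}

# 1-d Gaussian mixture EM with deterministic quantile initialization.
gmm1d_em <- function(x, k = 3, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k))
  sdev <- rep(stats::sd(x) / k, k)
  sdev[sdev <= 0] <- 1e-6
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  post <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sdev[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    post <- dens / rowsum_d
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * x) / nk
    sdev <- sqrt(colSums(post * (x - rep(mu, each = n))^2) / nk)
    sdev[sdev < 1e-8] <- 1e-8
    if (it > 1 &&
        abs(ll - ll_trace[it - 1]) < tol * (abs(ll_trace[it - 1]) + 1)) {
      return(list(means = mu, sds = sdev, weights = w, post = post,
                  loglik_trace = ll_trace, converged = TRUE))
    }
  }
  cond <- errorCondition(
    sprintf("EM did not converge in %d iterations", max_iter),
    loglik_trace = ll_trace,
    class = c("deepgwas_convergence_error", "error"))
  stop(cond)
}

#' Rotate a volume about one axis with trilinear interpolation
#'
#' In-plane rotation about the chosen axis around the volume center;
#' samples falling outside the input are zero-filled. Output shape equals
#' input shape.
#'
#' @param volume 3D numeric array.
#' @param angle rotation angle in degrees.
#' @param axis `"x"`, `"y"`, or `"z"` (default; axial in-plane rotation).
#' @return rotated 3D array.
#' @export
rotate_volume <- function(volume, angle, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  perm <- switch(axis, z = c(1, 2, 3), x = c(2, 3, 1), y = c(1, 3, 2))
  v <- if (axis == "z") volume else aperm(volume, perm)
  d <- dim(v)
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  th <- angle * pi / 180
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  gx <- rep(seq_len(nx), times = ny) - cx
  gy <- rep(seq_len(ny), each = nx) - cy
  # inverse mapping: source coordinates for each output voxel
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy

  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  vm <- matrix(v, nrow = nx * ny, ncol = nz)
  gather <- function(xi, yi) {
    valid <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    idx <- ifelse(valid, xi + (yi - 1) * nx, 1L)
    vm[idx, , drop = FALSE] * valid
  }
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  out <- gather(x0, y0) * w00 + gather(x0 + 1L, y0) * w10 +
         gather(x0, y0 + 1L) * w01 + gather(x0 + 1L, y0 + 1L) * w11
  out <- array(out, d)
  if (axis != "z") out <- aperm(out, order(perm))
  out
}

#' Rotation augmentation for training volumes
#'
#' Produces one rotated copy per angle; the paper-default angles are
#' -20, -10, -5, 5, 10 and 20 degrees, so each training image contributes
#' six additional images. The original volume is not included in the
#' returned list; augmentation is intended for training data only.
#'
#' @param volume 3D numeric array.
#' @param angles rotation angles in degrees.
#' @param axis rotation axis, see [rotate_volume()].
#' @return list of rotated volumes, one per angle.
#' @export
augment_rotations <- function(volume,
                              angles = c(-20, -10, -5, 5, 10, 20),
                              axis = "z") {
  if (!all(is.finite(angles))) stopf("angles must be finite")
  lapply(angles, function(a) rotate_volume(volume, a, axis = axis))
}
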