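# Minimal 3D convolutional network engine.
#
# A network is a plain list of layer records; convolution and pooling run
# through the package's C++ kernels, everything else is vectorized R.
# Tensors are (x, y, z, channel, batch); dense activations are
# (batch x units). All computation is single-threaded and deterministic
# given the ambient RNG state (dropout masks, shuffling).

layer_conv <- function(in_channels, out_channels, kernel) {
  fan_in <- kernel^3 * in_channels
  W <- array(rnorm(kernel^3 * in_channels * out_channels,
                   sd = sqrt(2 / fan_in)),
             c(kernel, kernel, kernel, in_channels, out_channels))
  list(type = "conv", W = W, b = numeric(out_channels))
}

layer_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

layer_bnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "bnorm", gamma = rep(1, channels), beta = numeric(channels),
       rmean = numeric(channels), rvar = rep(1, channels),
       momentum = momentum, eps = eps)
}

layer_relu <- function() list(type = "relu")
layer_pool <- function(size = 2) list(type = "pool", size = size)
layer_flatten <- function() list(type = "flatten")
layer_dropout <- function(p) list(type = "dropout", p = p)

# Per-channel mean/variance of a (x,y,z,C,N) tensor.
channel_stats <- function(x) {
  d <- dim(x)
  s <- prod(d[1:3])
  x3 <- x
  dim(x3) <- c(s, d[4], d[5])
  cs <- colSums(x3)                      # C x N sums over space
  cs2 <- colSums(x3 * x3)
  m <- s * d[5]
  mu <- rowSums(cs) / m
  v <- rowSums(cs2) / m - mu^2
  list(mean = mu, var = pmax(v, 0), m = m)
}

bcast_channel <- function(vals, d) {
  # expand per-channel vector to (x,y,z,C,N) via recycling over batch
  array(rep(vals, each = prod(d[1:3])), d)
}

nn_forward <- function(layers, x, training = FALSE, tap = NA_integer_) {
  caches <- vector("list", length(layers))
  tap_out <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    switch(ly$type,
      conv = {
        caches[[i]] <- list(x = x)
        x <- .conv3d_fwd(x, ly$W, ly$b)
      },
      relu = {
        x <- pmax(x, 0)
        caches[[i]] <- list(pos = x > 0)
      },
      pool = {
        caches[[i]] <- list(in_dim = dim(x))
        p <- .maxpool3d_fwd(x, ly$size)
        caches[[i]]$argmax <- p$argmax
        x <- p$y
      },
      bnorm = {
        d <- dim(x)
        if (training) {
          st <- channel_stats(x)
          if (!isTRUE(ly$initialized)) {
            # warm-start running statistics from the first batch so that
            # short trainings still get calibrated inference activations
            layers[[i]]$rmean <- st$mean
            layers[[i]]$rvar <- st$var
            layers[[i]]$initialized <- TRUE
          } else {
            layers[[i]]$rmean <- ly$momentum * ly$rmean +
              (1 - ly$momentum) * st$mean
            layers[[i]]$rvar <- ly$momentum * ly$rvar +
              (1 - ly$momentum) * st$var
          }
          invstd <- 1 / sqrt(st$var + ly$eps)
          xhat <- (x - bcast_channel(st$mean, d)) * bcast_channel(invstd, d)
          caches[[i]] <- list(xhat = xhat, invstd = invstd, m = st$m)
          x <- xhat * bcast_channel(ly$gamma, d) + bcast_channel(ly$beta, d)
        } else {
          invstd <- 1 / sqrt(ly$rvar + ly$eps)
          x <- (x - bcast_channel(ly$rmean, d)) * bcast_channel(invstd, d) *
            bcast_channel(ly$gamma, d) + bcast_channel(ly$beta, d)
        }
      },
      flatten = {
        d <- dim(x)
        caches[[i]] <- list(in_dim = d)
        x <- t(matrix(x, ncol = d[5]))
      },
      dense = {
        caches[[i]] <- list(x = x)
        x <- x %*% ly$W + rep(ly$b, each = nrow(x))
      },
      dropout = {
        if (training && ly$p > 0) {
          keep <- 1 - ly$p
          mask <- (matrix(runif(length(x)), nrow(x)) < keep) / keep
          caches[[i]] <- list(mask = mask)
          x <- x * mask
        }
      },
      stopf("unknown layer type: %s", ly$type))
    if (!is.na(tap) && i == tap) tap_out <- x
  }
  list(out = x, caches = caches, layers = layers, tap = tap_out)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  dx <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    switch(ly$type,
      conv = {
        g <- .conv3d_bwd(cc$x, ly$W, dx, i > 1L)
        grads[[i]] <- list(W = g$dw, b = g$db)
        dx <- g$dx
      },
      relu = {
        dx <- dx * cc$pos
      },
      pool = {
        d_in <- numeric(prod(cc$in_dim))
        d_in[cc$argmax] <- dx
        dim(d_in) <- cc$in_dim
        dx <- d_in
      },
      bnorm = {
        d <- dim(cc$xhat)
        s <- prod(d[1:3])
        x3 <- dx * cc$xhat
        dim(x3) <- c(s, d[4], d[5])
        dgamma <- rowSums(colSums(x3))
        x3 <- dx
        dim(x3) <- c(s, d[4], d[5])
        dbeta <- rowSums(colSums(x3))
        grads[[i]] <- list(gamma = dgamma, beta = dbeta)
        m <- cc$m
        coefs <- bcast_channel(ly$gamma * cc$invstd / m, d)
        dx <- coefs * (m * dx - bcast_channel(dbeta, d) -
                       cc$xhat * bcast_channel(dgamma, d))
      },
      flatten = {
        dx <- array(t(dx), cc$in_dim)
      },
      dense = {
        grads[[i]] <- list(W = crossprod(cc$x, dx), b = colSums(dx))
        dx <- dx %*% t(ly$W)
      },
      dropout = {
        if (!is.null(cc$mask)) dx <- dx * cc$mask
      })
  }
  list(dx = dx, grads = grads)
}

softmax_probs <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# Cross-entropy loss and logit gradient for 1..K integer targets.
softmax_ce <- function(logits, y_idx) {
  p <- softmax_probs(logits)
  n <- nrow(p)
  # no epsilon: an exactly-zero true-class probability means the logits
  # have blown past the exp() range, which training reports as divergence
  loss <- -mean(log(p[cbind(seq_len(n), y_idx)]))
  dy <- p
  dy[cbind(seq_len(n), y_idx)] <- dy[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, dlogits = dy / n, probs = p)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) {
      list(W = list(m = ly$W * 0, v = ly$W * 0),
           b = list(m = ly$b * 0, v = ly$b * 0))
    } else if (ly$type == "bnorm") {
      list(gamma = list(m = ly$gamma * 0, v = ly$gamma * 0),
           beta = list(m = ly$beta * 0, v = ly$beta * 0))
    } else NULL
  })
}

adam_step <- function(layers, grads, opt, lr, t, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      gv <- g[[nm]]
      if (l2 > 0 && nm == "W") gv <- gv + l2 * layers[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv * gv
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(layers = layers, opt = opt)
}

# Sum of squared weights for the L2 penalty term (conv + dense W only).
weight_sq_norm <- function(layers) {
  sum(vapply(layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) sum(ly$W^2) else 0
  }, numeric(1)))
}

n_params <- function(layers) {
  sum(vapply(layers, function(ly) {
    switch(ly$type,
           conv = length(ly$W) + length(ly$b),
           dense = length(ly$W) + length(ly$b),
           bnorm = 2L * length(ly$gamma),
           0L)
  }, numeric(1)))
}
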