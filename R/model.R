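# A scaled-down simple fully convolutional network (SFCN-style) classifier
# for 3D volumes: conv -> batchnorm -> ReLU -> average-pool blocks, a global
# average pool, and a single-unit dense output with sigmoid. Forward,
# backward and SGD are implemented here on top of the C++ conv kernels; no
# deep-learning framework is used, which keeps every weight visible to the
# relevance-propagation engine.

#' Build an untrained 3D convolutional classifier
#'
#' Architecture: `blocks` convolutional blocks (3x3x3 conv, batch
#' normalization, ReLU, and 2x2x2 average pooling in all but the last block),
#' followed by global average pooling and a single-unit dense output. Channel
#' widths double per block from `base_channels`, capped at `8 * base_channels`.
#' Weights use Glorot-uniform initialization; biases start at zero.
#'
#' @param grid input side length; must be divisible by `2^(blocks - 1)`.
#' @param blocks number of convolutional blocks (>= 2).
#' @param base_channels channels in the first block.
#' @param kernel odd convolution kernel width.
#' @param batchnorm include batch-normalization layers.
#' @param dropout dropout rate on the pooled feature vector during training
#'   (0 disables; documented grid values are 0.25 and 0.5).
#' @param weight_decay l2 penalty applied during SGD updates (documented grid
#'   values are 1e-2 and 1e-3).
#' @param seed RNG seed for the initialization (deterministic).
#' @return object of class `sfcn`.
#' @export
build_model <- function(grid = 48, blocks = 5, base_channels = 8, kernel = 3,
                        batchnorm = TRUE, dropout = 0, weight_decay = 0,
                        seed = 1) {
  stopifnot(blocks >= 2, is_odd(kernel), base_channels >= 1)
  down <- 2^(blocks - 1)
  if (grid %% down != 0 || grid / down < 1)
    stop("grid ", grid, " is incompatible with ", blocks,
         " blocks: it must be divisible by 2^(blocks-1) = ", down)
  channels <- pmin(base_channels * 2^(seq_len(blocks) - 1), 8 * base_channels)

  glorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  }
  layers <- list()
  with_seed(seed, {
    cin <- 1L
    for (b in seq_len(blocks)) {
      cout <- channels[b]
      w <- array(glorot(kernel^3 * cin, kernel^3 * cout, kernel^3 * cin * cout),
                 c(kernel, kernel, kernel, cin, cout))
      layers[[length(layers) + 1L]] <-
        list(kind = "conv3d", w = w, b = numeric(cout), kernel = kernel)
      if (batchnorm)
        layers[[length(layers) + 1L]] <-
          list(kind = "batchnorm", gamma = rep(1, cout), beta = numeric(cout),
               mean = numeric(cout), var = rep(1, cout), eps = 1e-3,
               momentum = 0.9)
      layers[[length(layers) + 1L]] <- list(kind = "relu")
      if (b < blocks)
        layers[[length(layers) + 1L]] <- list(kind = "pool", size = 2L)
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- list(kind = "global_pool")
    layers[[length(layers) + 1L]] <-
      list(kind = "dense_output", w = glorot(cin, 1, cin), b = 0)
  })
  m <- structure(
    list(layers = layers, grid = grid, blocks = blocks, channels = channels,
         kernel = kernel, sigmoid = TRUE, fused = FALSE, trained = FALSE,
         fold_id = NA_integer_, dropout = dropout,
         weight_decay = weight_decay, seed = seed),
    class = "sfcn")
  m$n_params <- count_params(m)
  m
}

#' Number of trainable parameters in a model
#' @param model an `sfcn` model.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    switch(l$kind,
      conv3d = length(l$w) + length(l$b),
      batchnorm = length(l$gamma) + length(l$beta),
      dense_output = length(l$w) + 1L,
      0L)
  }, 0))
}

#' @export
print.sfcn <- function(x, ...) {
  cat(sprintf(
    "<sfcn> grid %d^3, %d blocks (%s), %s params, %s%s%s\n",
    x$grid, x$blocks, paste(x$channels, collapse = "-"),
    format(x$n_params, big.mark = ","),
    if (x$trained) "trained" else "untrained",
    if (x$fused) ", fused" else "",
    if (x$sigmoid) "" else ", logit mode"))
  invisible(x)
}

# Broadcast a per-channel vector over a (V, C, N)-shaped flat array.
#' @noRd
bc_channel <- function(vec, V, N) rep(rep(vec, each = V), times = N)

# Forward pass over a 5-d batch (D, H, W, C=1, N). Returns logits, sigmoid
# predictions, and (optionally) recorded layer inputs and training caches.
#' @noRd
model_forward <- function(model, x, training = FALSE, record = FALSE,
                          dropout_mask = NULL) {
  nl <- length(model$layers)
  acts <- if (record) vector("list", nl) else NULL
  caches <- if (training) vector("list", nl) else NULL
  for (li in seq_len(nl)) {
    l <- model$layers[[li]]
    if (record) acts[[li]] <- x
    if (l$kind == "conv3d") {
      if (training) caches[[li]] <- list(x = x)
      x <- .conv3d_fwd(x, l$w, l$b)
    } else if (l$kind == "batchnorm") {
      d <- dim(x); V <- prod(d[1:3]); C <- d[4]; N <- d[5]
      flat <- x; dim(flat) <- c(V, C * N)
      if (training) {
        sums <- colSums(flat); dim(sums) <- c(C, N)
        mu <- rowSums(sums) / (V * N)
        sq <- colSums(flat^2); dim(sq) <- c(C, N)
        vv <- pmax(rowSums(sq) / (V * N) - mu^2, 0)
        model$layers[[li]]$mean <- l$momentum * l$mean + (1 - l$momentum) * mu
        model$layers[[li]]$var <- l$momentum * l$var + (1 - l$momentum) * vv
      } else {
        mu <- l$mean; vv <- l$var
      }
      invstd <- 1 / sqrt(vv + l$eps)
      xhat <- (as.vector(x) - bc_channel(mu, V, N)) * bc_channel(invstd, V, N)
      y <- xhat * bc_channel(l$gamma, V, N) + bc_channel(l$beta, V, N)
      if (training) caches[[li]] <- list(xhat = xhat, invstd = invstd, dims = d)
      x <- array(y, d)
    } else if (l$kind == "relu") {
      if (training) caches[[li]] <- list(mask = x > 0)
      x <- pmax(x, 0)
    } else if (l$kind == "pool") {
      if (training) caches[[li]] <- list(dims = dim(x))
      x <- .avgpool_fwd(x, l$size)
    } else if (l$kind == "global_pool") {
      d <- dim(x); V <- prod(d[1:3])
      if (training) caches[[li]] <- list(dims = d)
      flat <- x; dim(flat) <- c(V, d[4] * d[5])
      x <- matrix(colSums(flat) / V, d[4], d[5])
      if (training && model$dropout > 0) {
        if (is.null(dropout_mask))
          dropout_mask <- matrix(
            (runif(length(x)) >= model$dropout) / (1 - model$dropout),
            nrow(x), ncol(x))
        x <- x * dropout_mask
        caches[[li]]$dropout_mask <- dropout_mask
      }
    } else if (l$kind == "dense_output") {
      if (training) caches[[li]] <- list(feat = x)
      x <- as.vector(crossprod(x, l$w)) + l$b
    } else stop("unknown layer kind: ", l$kind)
  }
  logit <- x
  list(logit = logit, yhat = plogis(logit), acts = acts, caches = caches,
       model = model)
}

# Backward pass; `dlogit` is dLoss/dlogit (length N). Returns per-layer
# gradient list aligned with model$layers.
#' @noRd
model_backward <- function(model, fw, dlogit) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  g <- dlogit
  for (li in rev(seq_len(nl))) {
    l <- model$layers[[li]]
    cc <- fw$caches[[li]]
    if (l$kind == "dense_output") {
      grads[[li]] <- list(gw = as.vector(cc$feat %*% g), gb = sum(g))
      g <- outer(l$w, g)                       # C x N
    } else if (l$kind == "global_pool") {
      if (!is.null(cc$dropout_mask)) g <- g * cc$dropout_mask
      d <- cc$dims; V <- prod(d[1:3])
      g <- array(rep(as.vector(g), each = V) / V, d)
    } else if (l$kind == "pool") {
      g <- .pool_upsample(g, l$size, 1 / l$size^3)
    } else if (l$kind == "relu") {
      g <- g * cc$mask
    } else if (l$kind == "batchnorm") {
      d <- cc$dims; V <- prod(d[1:3]); C <- d[4]; N <- d[5]; M <- V * N
      gv <- as.vector(g)
      per_channel <- function(v) {
        dim(v) <- c(V, C, N)
        s <- colSums(v); dim(s) <- c(C, N)
        rowSums(s)
      }
      dgamma <- per_channel(gv * cc$xhat)
      dbeta <- per_channel(gv)
      dxhat <- gv * bc_channel(l$gamma, V, N)
      t1 <- per_channel(dxhat)
      t2 <- per_channel(dxhat * cc$xhat)
      dx <- bc_channel(cc$invstd, V, N) / M *
        (M * dxhat - bc_channel(t1, V, N) - cc$xhat * bc_channel(t2, V, N))
      grads[[li]] <- list(ggamma = dgamma, gbeta = dbeta)
      g <- array(dx, d)
    } else if (l$kind == "conv3d") {
      gr <- .conv3d_bwd_weights(cc$x, g, l$kernel)
      grads[[li]] <- list(gw = gr$gw, gb = gr$gb)
      g <- .conv3d_bwd_input(g, l$w)
    }
  }
  grads
}

#' @noRd
sgd_update <- function(model, grads, lr) {
  wd <- model$weight_decay
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    gr <- grads[[li]]
    if (is.null(gr)) next
    if (l$kind %in% c("conv3d", "dense_output")) {
      model$layers[[li]]$w <- l$w - lr * (gr$gw + wd * l$w)
      model$layers[[li]]$b <- l$b - lr * gr$gb
    } else if (l$kind == "batchnorm") {
      model$layers[[li]]$gamma <- l$gamma - lr * gr$ggamma
      model$layers[[li]]$beta <- l$beta - lr * gr$gbeta
    }
  }
  model
}

# Stack a list of 3D volumes into the 5-d batch layout.
#' @noRd
stack_volumes <- function(volumes) {
  d <- dim(volumes[[1]])
  x <- array(0, c(d, 1L, length(volumes)))
  for (i in seq_along(volumes)) x[, , , 1L, i] <- volumes[[i]]
  x
}

#' Predict on a list of volumes
#'
#' @param model an `sfcn` model.
#' @param volumes list of 3D arrays matching the model grid.
#' @param batch mini-batch size for the forward pass.
#' @return numeric vector: sigmoid predictions in \[0, 1\], or raw logits if
#'   the model is in logit mode (see [strip_sigmoid()]).
#' @export
predict_volumes <- function(model, volumes, batch = 8) {
  if (!is.list(volumes)) volumes <- list(volumes)
  out <- numeric(length(volumes))
  idx <- split(seq_along(volumes), ceiling(seq_along(volumes) / batch))
  for (ii in idx) {
    fw <- model_forward(model, stack_volumes(volumes[ii]))
    out[ii] <- if (model$sigmoid) fw$yhat else fw$logit
  }
  out
}

#' Remove the sigmoid from the output layer (logit mode)
#'
#' After surgery the model returns the unbounded logit; the mapping is purely
#' monotone, so a logit of 0 corresponds to a sigmoid prediction of 0.5.
#'
#' @param model an `sfcn` model with sigmoid output.
#' @return the model in logit mode.
#' @export
strip_sigmoid <- function(model) {
  if (!model$sigmoid) {
    warning("model is already in logit mode; nothing to strip")
    return(model)
  }
  model$sigmoid <- FALSE
  model
}

#' Fuse batch-normalization layers into their preceding convolutions
#'
#' Uses the stored (inference) normalization statistics to rescale the
#' convolution weights and shift its biases, then removes the
#' batch-normalization layers. The fused model is functionally equivalent in
#' inference mode.
#'
#' @param model an `sfcn` model.
#' @return model without batchnorm layers (`fused = TRUE`).
#' @export
fuse_batchnorm <- function(model) {
  layers <- list()
  prev_conv <- 0L
  for (l in model$layers) {
    if (l$kind == "batchnorm") {
      if (prev_conv == 0L)
        stop("batchnorm layer has no preceding convolution to fuse into")
      cv <- layers[[prev_conv]]
      scale <- l$gamma / sqrt(l$var + l$eps)
      k3ci <- prod(dim(cv$w)[1:4])
      w <- cv$w * rep(scale, each = k3ci)
      b <- (cv$b - l$mean) * scale + l$beta
      layers[[prev_conv]]$w <- w
      layers[[prev_conv]]$b <- b
      prev_conv <- 0L
    } else {
      layers[[length(layers) + 1L]] <- l
      prev_conv <- if (l$kind == "conv3d") length(layers) else 0L
    }
  }
  model$layers <- layers
  model$fused <- TRUE
  model
}

# Re-estimate batch-normalization statistics from data ("precise BN"): one
# forward sweep accumulating per-channel means/variances, replacing the
# momentum-tracked running statistics. At desk scale (few SGD steps) the
# tracked statistics lag the weights badly enough to corrupt inference, so
# the trainer refreshes them before every validation pass.
#' @noRd
refresh_batchnorm_stats <- function(model, volumes, batch = 8) {
  bn_idx <- which(vapply(model$layers, `[[`, "", "kind") == "batchnorm")
  if (!length(bn_idx)) return(model)
  acc <- lapply(bn_idx, function(i) list(s = 0, s2 = 0, n = 0))
  names(acc) <- bn_idx
  idx <- split(seq_along(volumes), ceiling(seq_along(volumes) / batch))
  for (ii in idx) {
    x <- stack_volumes(volumes[ii])
    for (li in seq_along(model$layers)) {
      l <- model$layers[[li]]
      if (l$kind == "conv3d") {
        x <- .conv3d_fwd(x, l$w, l$b)
      } else if (l$kind == "batchnorm") {
        d <- dim(x); V <- prod(d[1:3]); C <- d[4]; N <- d[5]
        flat <- x; dim(flat) <- c(V, C * N)
        s <- colSums(flat); dim(s) <- c(C, N)
        s2 <- colSums(flat^2); dim(s2) <- c(C, N)
        key <- as.character(li)
        acc[[key]]$s <- acc[[key]]$s + rowSums(s)
        acc[[key]]$s2 <- acc[[key]]$s2 + rowSums(s2)
        acc[[key]]$n <- acc[[key]]$n + V * N
        # normalize this batch with its own statistics (training behaviour)
        mu <- rowSums(s) / (V * N)
        vv <- pmax(rowSums(s2) / (V * N) - mu^2, 0)
        invstd <- 1 / sqrt(vv + l$eps)
        x <- array((as.vector(x) - bc_channel(mu, V, N)) *
                     bc_channel(invstd * l$gamma, V, N) +
                     bc_channel(l$beta, V, N), d)
      } else if (l$kind == "relu") {
        x <- pmax(x, 0)
      } else if (l$kind == "pool") {
        x <- .avgpool_fwd(x, l$size)
      } else break                         # stats collected; head irrelevant
    }
  }
  for (key in names(acc)) {
    a <- acc[[key]]
    li <- as.integer(key)
    mu <- a$s / a$n
    model$layers[[li]]$mean <- mu
    model$layers[[li]]$var <- pmax(a$s2 / a$n - mu^2, 0)
  }
  model
}

# Randomize batch-normalization statistics/parameters; makes fusion
# non-trivial for equivalence testing on untrained models.
#' @noRd
perturb_batchnorm <- function(model, seed = 1) {
  with_seed(seed, {
    for (li in seq_along(model$layers)) {
      l <- model$layers[[li]]
      if (l$kind != "batchnorm") next
      n <- length(l$gamma)
      model$layers[[li]]$gamma <- runif(n, 0.5, 1.5)
      model$layers[[li]]$beta <- rnorm(n, 0, 0.3)
      model$layers[[li]]$mean <- rnorm(n, 0, 0.5)
      model$layers[[li]]$var <- runif(n, 0.5, 2)
    }
  })
  model
}

# Zero all biases and normalization shifts: a bias-free variant used by the
# conservation analyses.
#' @noRd
zero_biases <- function(model) {
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$kind %in% c("conv3d", "dense_output"))
      model$layers[[li]]$b <- l$b * 0
    if (l$kind == "batchnorm") {
      model$layers[[li]]$beta <- l$beta * 0
      model$layers[[li]]$mean <- l$mean * 0
    }
  }
  model
}

#' Export a backend-neutral architecture manifest
#'
#' @param model an `sfcn` model.
#' @param path optional JSON output path.
#' @return manifest list (invisibly written to `path` when given).
#' @export
model_manifest <- function(model, path = NULL) {
  man <- list(
    grid = model$grid, blocks = model$blocks, channels = model$channels,
    kernel = model$kernel, n_params = model$n_params,
    sigmoid = model$sigmoid, fused = model$fused, trained = model$trained,
    fold_id = model$fold_id,
    layers = lapply(model$layers, function(l) {
      out <- list(kind = l$kind)
      if (l$kind == "conv3d") out$shape <- dim(l$w)
      if (l$kind == "dense_output") out$units_in <- length(l$w)
      if (l$kind == "pool") out$size <- l$size
      out
    }))
  if (!is.null(path))
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
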