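# Independent brute-force LRP oracle: materializes the explicit contribution
# matrix of a dense layer and redistributes relevance by explicit loops.
# Deliberately implemented with scalar arithmetic, no shared code with the
# package's layered engine.

oracle_dense <- function(a, w, r, b = 0, rule = "generic",
                         epsilon = 0, alpha = 1, beta = 0) {
  w <- as.matrix(w)
  M <- nrow(w); N <- ncol(w)
  b <- rep_len(b, N)
  out <- numeric(M)
  if (rule == "flat") {
    for (n in seq_len(N)) for (m in seq_len(M)) out[m] <- out[m] + r[n] / M
    return(out)
  }
  for (n in seq_len(N)) {
    contrib <- numeric(M)
    for (m in seq_len(M)) contrib[m] <- a[m] * w[m, n]
    if (rule %in% c("generic", "epsilon")) {
      z <- sum(contrib) + b[n]
      z <- z + epsilon * (if (z >= 0) 1 else -1) * (epsilon > 0)
      if (z == 0) next
      for (m in seq_len(M)) out[m] <- out[m] + contrib[m] / z * r[n]
    } else if (rule == "alphabeta") {
      zp <- sum(pmax(contrib, 0)) + max(b[n], 0)
      zn <- sum(pmin(contrib, 0)) + min(b[n], 0)
      for (m in seq_len(M)) {
        if (alpha > 0 && zp != 0)
          out[m] <- out[m] + alpha * max(contrib[m], 0) / zp * r[n]
        if (beta > 0 && zn != 0)
          out[m] <- out[m] - beta * min(contrib[m], 0) / zn * r[n]
      }
    } else stop("unknown rule")
  }
  out
}

# Materialize a 3D same-padded convolution (single channel in/out) as an
# explicit voxels x voxels matrix, by explicit index arithmetic.
conv_as_matrix <- function(w3, dims) {
  K <- dim(w3)[1]
  P <- (K - 1) / 2
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  nv <- D * H * W
  idx <- function(i, j, k) i + D * (j - 1) + D * H * (k - 1)
  mat <- matrix(0, nv, nv)
  for (k in seq_len(W)) for (j in seq_len(H)) for (i in seq_len(D)) {
    for (dz in seq_len(K)) for (dy in seq_len(K)) for (dx in seq_len(K)) {
      ii <- i + dx - 1 - P; jj <- j + dy - 1 - P; kk <- k + dz - 1 - P
      if (ii >= 1 && ii <= D && jj >= 1 && jj <= H && kk >= 1 && kk <= W)
        mat[idx(ii, jj, kk), idx(i, j, k)] <-
          mat[idx(ii, jj, kk), idx(i, j, k)] + w3[dx, dy, dz]
    }
  }
  mat
}

# Run a single conv layer through the package engine's conv-space rule.
engine_conv_rule <- function(a3, w3, r3, rule = "generic",
                             epsilon = 0, alpha = 1, beta = 0, bias = 0) {
  dims <- dim(a3)
  a <- array(a3, c(dims, 1, 1))
  r <- array(r3, c(dims, 1, 1))
  w <- array(w3, c(dim(w3), 1, 1))
  l <- list(kind = "conv3d", w = w, b = bias, kernel = dim(w3)[1])
  log <- relmap3d:::new_drop_log()
  out <- switch(rule,
    generic = ,
    epsilon = relmap3d:::conv_lrp_epsilon(a, l, r, epsilon, log),
    alphabeta = relmap3d:::conv_lrp_alphabeta(a, l, r, alpha, beta, log),
    flat = relmap3d:::conv_lrp_flat(a, l, r, FALSE))
  array(out, dims)
}

# Small deterministic fixtures shared across test files.
tiny_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_atlas(grid = 16, n_regions = 6,
                                                  seed = 101)
    cache
  }
})

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(6, tiny_atlas(), lesion_regions = 2,
                                effect = 0.3, noise_sd = 0.05, seed = 102)
    cache
  }
})
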