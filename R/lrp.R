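# Composite Layerwise Relevance Propagation (LRP).
#
# The prediction logit is redistributed backwards through the fused,
# logit-mode classifier, layer by layer, onto the input voxels. Three rules
# are implemented:
#   * epsilon: proportional redistribution with a sign-stabilized epsilon in
#     the denominator (epsilon = 0 recovers the original LRP rule);
#   * alpha-beta: positive and negative contributions are normalized
#     separately and reweighted by alpha and beta (alpha - beta = 1);
#   * flat: each downstream neuron splits its relevance uniformly over the
#     upstream neurons it is connected to.
# Biases contribute to the denominators (they shape the activations) but
# receive no outgoing relevance; with bias-free weights each rule conserves
# the layer-wise relevance sum exactly. Zero denominators absorb the affected
# relevance; absorbed events are counted and reported on the resulting map.

#' @noRd
sign1 <- function(x) ifelse(x >= 0, 1, -1)

#' @noRd
new_drop_log <- function() new.env(parent = emptyenv())

#' @noRd
log_drops <- function(log, n, amount) {
  if (is.null(log) || n == 0) return(invisible())
  log$n <- (log$n %||% 0L) + n
  log$amount <- (log$amount %||% 0) + amount
  invisible()
}

# Safe ratio r / z with zero-denominator absorption.
#' @noRd
safe_ratio <- function(r, z, log = NULL) {
  bad <- z == 0
  out <- r
  out[!bad] <- r[!bad] / z[!bad]
  if (any(bad)) {
    dropped <- bad & r != 0
    log_drops(log, sum(dropped), sum(abs(r[dropped])))
    out[bad] <- 0
  }
  out
}

#' Dense-layer LRP: proportional (generic) rule
#'
#' Redistributes downstream relevance `r` over upstream activations `a`
#' through weight matrix `w` in proportion to each unit's contribution
#' `a_m w_mn` to the downstream pre-activation.
#'
#' @param a upstream activations (length M).
#' @param w M x N weight matrix (or length-M vector for a single output).
#' @param r downstream relevance (length N).
#' @param b downstream biases (enter the denominator, receive no relevance).
#' @return upstream relevance (length M).
#' @export
lrp_generic <- function(a, w, r, b = 0) lrp_epsilon(a, w, r, b, epsilon = 0)

#' Dense-layer LRP: epsilon rule
#'
#' As [lrp_generic()], with a sign-stabilized `epsilon` added to each
#' denominator. Large epsilon absorbs relevance (the maps fade to zero);
#' `epsilon = 0` is exact proportional redistribution.
#'
#' @inheritParams lrp_generic
#' @param epsilon nonnegative stabilizer.
#' @export
lrp_epsilon <- function(a, w, r, b = 0, epsilon = 0) {
  w <- as.matrix(w)
  z <- as.vector(crossprod(w, a)) + b
  zs <- if (epsilon > 0) z + epsilon * sign1(z) else z
  s <- safe_ratio(r, zs)
  as.vector(w %*% s) * a
}

#' Dense-layer LRP: alpha-beta rule
#'
#' Positive and negative contributions `(a_m w_mn)^+ / (a_m w_mn)^-` are
#' normalized by their own column sums and combined as `alpha * positive -
#' beta * negative`; `alpha - beta = 1` preserves the total relevance.
#'
#' @inheritParams lrp_generic
#' @param alpha weight on positive contributions (>= 0).
#' @param beta weight on negative contributions (>= 0); `alpha - beta` must
#'   equal 1.
#' @export
lrp_alphabeta <- function(a, w, r, b = 0, alpha = 1, beta = alpha - 1) {
  stopifnot(alpha >= 0, beta >= 0)
  if (abs(alpha - beta - 1) > 1e-12)
    stop("alpha - beta must equal 1 (got alpha=", alpha, ", beta=", beta, ")")
  w <- as.matrix(w)
  contrib <- a * w                      # M x N contribution matrix
  cp <- pmax(contrib, 0)
  cn <- pmin(contrib, 0)
  b <- rep_len(b, ncol(w))
  zp <- colSums(cp) + pmax(b, 0)
  zn <- colSums(cn) + pmin(b, 0)
  sp <- if (alpha > 0) safe_ratio(alpha * r, zp) else numeric(ncol(w))
  sn <- if (beta > 0) safe_ratio(beta * r, zn) else numeric(ncol(w))
  as.vector(cp %*% sp) - as.vector(cn %*% sn)
}

#' Dense-layer LRP: flat rule
#'
#' Each downstream neuron splits its relevance uniformly across all `M`
#' upstream neurons, ignoring weights and activations.
#'
#' @param M number of upstream neurons.
#' @param r downstream relevance vector.
#' @export
lrp_flat <- function(M, r) rep(sum(r) / M, M)

#' Composite rule assignment for a fused classifier
#'
#' The composite strategy keeps the most salient explanation at the output
#' (epsilon rule on the dense layer), upweights positive evidence in the
#' central convolutions (alpha-beta), and smooths fine detail near the input
#' (flat rule on the first convolution). Pooling layers are treated as
#' fixed-weight convolutions under the epsilon rule. The `generic` preset
#' applies the epsilon rule everywhere.
#'
#' @param model a fused, logit-mode `sfcn` model.
#' @param preset `"composite"` or `"generic"`.
#' @param alpha,beta alpha-beta rule parameters; `alpha - beta` must be 1.
#'   The default (1, 0) keeps only positive evidence.
#' @param epsilon sign-stabilized epsilon for epsilon-rule layers; the tiny
#'   default acts as a numerical stabilizer with negligible absorption. Set
#'   to 0 for exact conservation analyses.
#' @param flat_count_padding if `TRUE`, the flat rule counts zero-padded
#'   kernel positions at borders as connections (dialect switch); the default
#'   counts only real upstream neurons.
#' @return object of class `rule_assignment`.
#' @export
rule_assignment <- function(model, preset = c("composite", "generic"),
                            alpha = 1, beta = alpha - 1, epsilon = 1e-9,
                            flat_count_padding = FALSE) {
  preset <- match.arg(preset)
  if (abs(alpha - beta - 1) > 1e-12 || alpha < 0 || beta < 0)
    stop("alpha-beta rule requires alpha >= 0, beta >= 0, alpha - beta = 1")
  kinds <- vapply(model$layers, `[[`, "", "kind")
  rules <- rep("pass", length(kinds))
  conv_idx <- which(kinds == "conv3d")
  if (preset == "composite") {
    rules[conv_idx] <- "alphabeta"
    rules[conv_idx[1]] <- "flat"
  } else {
    rules[conv_idx] <- "epsilon"
  }
  rules[kinds %in% c("pool", "global_pool")] <- "epsilon"
  rules[kinds == "dense_output"] <- "epsilon"
  structure(list(rules = rules, preset = preset, alpha = alpha, beta = beta,
                 epsilon = epsilon, flat_count_padding = flat_count_padding),
            class = "rule_assignment")
}

#' @export
print.rule_assignment <- function(x, ...) {
  cat(sprintf(
    "<rule_assignment> %s (alpha=%g, beta=%g, epsilon=%g)\n  layers: %s\n",
    x$preset, x$alpha, x$beta, x$epsilon, paste(x$rules, collapse = " ")))
  invisible(x)
}

# ---- convolutional-space rule implementations ------------------------------

#' @noRd
conv_lrp_epsilon <- function(a, l, r, epsilon, log) {
  z <- .conv3d_fwd(a, l$w, l$b)
  if (epsilon > 0) z <- z + epsilon * sign1(z)
  s <- safe_ratio(r, z, log)
  a * .conv3d_bwd_input(s, l$w)
}

#' @noRd
conv_lrp_alphabeta <- function(a, l, r, alpha, beta, log) {
  wp <- pmax(l$w, 0); wn <- pmin(l$w, 0)
  ap <- pmax(a, 0);  an <- pmin(a, 0)
  zp <- .conv3d_fwd(ap, wp, pmax(l$b, 0)) + .conv3d_fwd(an, wn, numeric(length(l$b)))
  out <- 0
  if (alpha > 0) {
    sp <- safe_ratio(alpha * r, zp, log)
    out <- ap * .conv3d_bwd_input(sp, wp) + an * .conv3d_bwd_input(sp, wn)
  }
  if (beta > 0) {
    zn <- .conv3d_fwd(ap, wn, pmin(l$b, 0)) + .conv3d_fwd(an, wp, numeric(length(l$b)))
    sn <- safe_ratio(beta * r, zn, log)
    out <- out - (ap * .conv3d_bwd_input(sn, wn) + an * .conv3d_bwd_input(sn, wp))
  }
  out
}

#' @noRd
conv_lrp_flat <- function(a, l, r, count_padding) {
  wd <- dim(l$w)
  ones_k <- array(1, wd)
  if (count_padding) {
    cnt <- array(prod(wd[1:4]), dim(r))
  } else {
    cnt <- .conv3d_fwd(array(1, dim(a)), ones_k, numeric(wd[5]))
  }
  .conv3d_bwd_input(r / cnt, ones_k)
}

#' @noRd
pool_lrp_epsilon <- function(a, l, r, epsilon, log) {
  z <- .avgpool_fwd(a, l$size) * l$size^3   # block sums
  if (epsilon > 0) z <- z + epsilon * sign1(z)
  s <- safe_ratio(r, z, log)
  a * .pool_upsample(s, l$size, 1)
}

#' @noRd
gpool_lrp_epsilon <- function(a, r, epsilon, log) {
  d <- dim(a); V <- prod(d[1:3])
  flat <- a; dim(flat) <- c(V, d[4] * d[5])
  z <- colSums(flat)                        # voxel sums per channel
  if (epsilon > 0) z <- z + epsilon * sign1(z)
  s <- safe_ratio(as.vector(r) * V, z, log) # seed scaled: weights are 1/V
  a * array(rep(s, each = V) / V, d)
}

#' Explain a single prediction with composite LRP
#'
#' Runs a recorded forward pass and redistributes the output logit backwards
#' onto the input voxels. Positive relevance is visual evidence in favor of
#' the positive class; with the all-generic rule set, zero epsilon and a
#' bias-free network the voxel relevances sum exactly to the logit.
#'
#' @param model a fused (`fuse_batchnorm()`), logit-mode (`strip_sigmoid()`)
#'   `sfcn` model.
#' @param volume 3D array matching the model grid.
#' @param rules a [rule_assignment()]; defaults to the composite strategy.
#' @return object of class `relevance_map`: `values` (3D array of voxel
#'   relevance, same grid as the input), `yhat_logit`, `yhat` (sigmoid
#'   scale), `rules`, `fold_id`, and `absorbed` (count and magnitude of
#'   relevance absorbed at zero denominators).
#' @export
explain <- function(model, volume, rules = NULL) {
  if (model$sigmoid)
    stop("model must be in logit mode; call strip_sigmoid() first")
  kinds <- vapply(model$layers, `[[`, "", "kind")
  if (any(kinds == "batchnorm"))
    stop("model contains batchnorm layers; call fuse_batchnorm() first")
  if (length(dim(volume)) != 3 || !all(dim(volume) == model$grid))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match model grid ", model$grid)
  rules <- rules %||% rule_assignment(model, "composite")

  fw <- model_forward(model, stack_volumes(list(volume)), record = TRUE)
  log <- new_drop_log()
  r <- fw$logit                              # seed relevance at the output
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    a <- fw$acts[[li]]
    rule <- rules$rules[li]
    if (l$kind == "relu") next
    if (l$kind == "dense_output") {
      r <- matrix(lrp_epsilon(as.vector(a), l$w, r, l$b, rules$epsilon),
                  ncol = 1)
    } else if (l$kind == "global_pool") {
      r <- gpool_lrp_epsilon(a, r, rules$epsilon, log)
    } else if (l$kind == "pool") {
      r <- pool_lrp_epsilon(a, l, r, rules$epsilon, log)
    } else if (l$kind == "conv3d") {
      r <- switch(rule,
        flat = conv_lrp_flat(a, l, r, rules$flat_count_padding),
        alphabeta = conv_lrp_alphabeta(a, l, r, rules$alpha, rules$beta, log),
        conv_lrp_epsilon(a, l, r, rules$epsilon, log))
    } else stop("cannot propagate through layer kind: ", l$kind)
  }
  structure(
    list(values = array(r, dim(volume)),
         yhat_logit = fw$logit, yhat = plogis(fw$logit),
         rules = rules, fold_id = model$fold_id,
         absorbed = list(n = log$n %||% 0L, amount = log$amount %||% 0)),
    class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> %s, yhat=%.4f (logit %.4f), sum(r)=%.5f, %d absorbed\n",
    paste(dim(x$values), collapse = "x"), x$yhat, x$yhat_logit,
    sum(x$values), x$absorbed$n))
  invisible(x)
}

#' Ensemble explanation across fold models
#'
#' Averages the sigmoid predictions and the voxel-wise relevance over a list
#' of models (all on the same grid).
#'
#' @param models list of fused, logit-mode `sfcn` models.
#' @param volume 3D array.
#' @param rules optional shared [rule_assignment()].
#' @return a `relevance_map` whose values and predictions are the voxel-wise
#'   and arithmetic means over the member models.
#' @export
ensemble_explain <- function(models, volume, rules = NULL) {
  stopifnot(length(models) >= 1)
  grids <- vapply(models, `[[`, 0, "grid")
  if (length(unique(grids)) != 1)
    stop("all ensemble members must share one grid")
  maps <- lapply(models, explain, volume = volume, rules = rules)
  out <- maps[[1]]
  out$values <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out$yhat <- mean(vapply(maps, `[[`, 0, "yhat"))
  out$yhat_logit <- mean(vapply(maps, `[[`, 0, "yhat_logit"))
  out$fold_id <- NA_integer_
  out$absorbed <- list(
    n = sum(vapply(maps, function(m) m$absorbed$n, 0L)),
    amount = sum(vapply(maps, function(m) m$absorbed$amount, 0)))
  out
}

#' Write a relevance map with its JSON sidecar
#'
#' @param map a `relevance_map`.
#' @param path output NIfTI path (`.nii` / `.nii.gz`); the sidecar replaces
#'   the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_relevance_map <- function(map, path) {
  write_nifti(map$values, path, description = "relmap3d relevance")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(yhat = map$yhat, yhat_logit = map$yhat_logit,
         fold_id = map$fold_id, preset = map$rules$preset,
         alpha = map$rules$alpha, beta = map$rules$beta,
         epsilon = map$rules$epsilon, absorbed = map$absorbed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
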