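# Quantitative validation battery for relevance maps: randomized null
# pipelines, true-positive averaging, percentile binarization with Dice
# curves, normalized cross-correlation, region-wise aggregation, and the
# iterative occlusion test with the area over the perturbation curve (AOPC).

#' Relevance maps from a null pipeline
#'
#' Three sanity-check pipelines, each sharing the full LRP machinery with the
#' task pipeline and substituting exactly one ingredient:
#' * `random_images`: inputs are replaced by draws from a voxel-wise normal
#'   distribution with the cohort mean and standard deviation;
#' * `random_weights`: the task model is replaced by an untrained model of
#'   the same architecture;
#' * `alt_task`: the task model is replaced by a model trained on an
#'   orthogonal attribute (e.g. the sex-linked signal), supplied as
#'   `alt_model`.
#'
#' @param kind one of `"random_images"`, `"random_weights"`, `"alt_task"`.
#' @param model fused, logit-mode task model (used directly by
#'   `random_images`; supplies the architecture for `random_weights`).
#' @param volumes list of input volumes.
#' @param rules optional [rule_assignment()] shared with the task pipeline.
#' @param alt_model fused, logit-mode alternative-task model (for `alt_task`).
#' @param sigma_scale multiplier on the voxel-wise standard deviation for
#'   `random_images` (0 degenerates to the constant mean image).
#' @param seed RNG seed for the random draws.
#' @param ... passed to [build_model()] for `random_weights`.
#' @return list of `relevance_map` objects, one per volume.
#' @export
null_pipeline_maps <- function(kind = c("random_images", "random_weights",
                                        "alt_task"),
                               model, volumes, rules = NULL, alt_model = NULL,
                               sigma_scale = 1, seed = 1, ...) {
  kind <- match.arg(kind)
  if (kind == "random_images") {
    d <- dim(volumes[[1]])
    n <- length(volumes)
    flat <- vapply(volumes, as.vector, numeric(prod(d)))
    mu <- rowMeans(flat)
    sdv <- apply(flat, 1, sd) * sigma_scale
    scrambled <- with_seed(seed, lapply(seq_len(n), function(i)
      array(rnorm(prod(d), mu, sdv), d)))
    return(lapply(scrambled, function(x) explain(model, x, rules)))
  }
  if (kind == "random_weights") {
    m0 <- build_model(grid = model$grid, seed = seed, ...)
    m0 <- strip_sigmoid(fuse_batchnorm(m0))
    return(lapply(volumes, function(x) explain(m0, x, rules)))
  }
  if (is.null(alt_model))
    stop("alt_task pipeline requires an alt_model trained on an orthogonal attribute")
  lapply(volumes, function(x) explain(alt_model, x, rules))
}

#' Average relevance map over true positives
#'
#' @param maps list of `relevance_map`s (or 3D arrays), one per case.
#' @param predictions sigmoid-scale predictions aligned with `maps`.
#' @param labels binary labels aligned with `maps`.
#' @return 3D array: voxel-wise mean over cases with `label == 1` and
#'   `prediction > 0.5`.
#' @export
average_true_positive_map <- function(maps, predictions, labels) {
  keep <- which(as.integer(labels) == 1L & predictions > 0.5)
  if (!length(keep)) stop("no true positives to average")
  vals <- lapply(maps[keep], map_values)
  Reduce(`+`, vals) / length(keep)
}

#' Binarize a map at a percentile threshold
#'
#' A voxel is set to 1 iff its value strictly exceeds the `p`-th percentile
#' of the map's values (so a constant map binarizes to all zeros).
#'
#' @param map 3D array or `relevance_map`.
#' @param p percentile in \[0, 100).
#' @return logical array of the same shape.
#' @export
binarize_percentile <- function(map, p) {
  stopifnot(p >= 0, p < 100)
  v <- map_values(map)
  v > quantile(v, p / 100, names = FALSE)
}

#' Sorensen-Dice overlap of two binary maps
#'
#' Implements the overlap as the intersection divided by the sum of the two
#' map sizes (so identical nonempty maps score 0.5); `conventional = TRUE`
#' doubles the numerator, giving the standard Dice coefficient.
#'
#' @param a,b binary/logical arrays on the same grid.
#' @param conventional use the conventional `2|A&B| / (|A|+|B|)` form.
#' @return overlap in \[0, 1\]; two empty maps score 0 (with a message).
#' @export
dice <- function(a, b, conventional = FALSE) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("both maps are empty; Dice defined as 0")
    return(0)
  }
  (if (conventional) 2 else 1) * sum(a & b) / denom
}

#' Dice curve over symmetric percentile thresholds
#'
#' @param avg_map average relevance map (3D array).
#' @param reference reference map `G` on the same grid.
#' @param percentiles thresholds in \[0, 100); both maps are binarized at the
#'   same percentile.
#' @param conventional see [dice()].
#' @param label pipeline label carried in the result.
#' @return data.frame of class `dice_curve`: `percentile`, `sdc`, `pipeline`.
#' @export
dice_curve <- function(avg_map, reference, percentiles = 0:99,
                       conventional = FALSE, label = "task") {
  sdc <- vapply(percentiles, function(p)
    dice(binarize_percentile(avg_map, p),
         binarize_percentile(reference, p), conventional), 0)
  structure(data.frame(percentile = percentiles, sdc = sdc, pipeline = label,
                       stringsAsFactors = FALSE),
            class = c("dice_curve", "data.frame"))
}

#' Normalized cross-correlation of two maps
#'
#' Pearson-style similarity over voxels, invariant to positive affine
#' rescaling of either map.
#'
#' @param a,b non-constant arrays on the same grid.
#' @return value in \[-1, 1\].
#' @export
ncc <- function(a, b) {
  a <- as.vector(map_values(a)); b <- as.vector(map_values(b))
  stopifnot(length(a) == length(b))
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0) stop("ncc is undefined for constant maps")
  sum(da * db) / sqrt(va * vb)
}

#' Aggregate a map over atlas regions
#'
#' @param map 3D array or `relevance_map`.
#' @param atlas a [synthetic_atlas()] (or integer label array) on the same grid.
#' @param stat `"mean"`, `"sum"` or `"max"`.
#' @return data.frame: `region`, `name` (when available), `value`.
#' @export
region_aggregate <- function(map, atlas, stat = c("mean", "sum", "max")) {
  stat <- match.arg(stat)
  labels <- if (inherits(atlas, "synthetic_atlas")) atlas$labels else atlas
  v <- map_values(map)
  stopifnot(identical(dim(v), dim(labels)))
  keep <- labels > 0
  agg <- tapply(v[keep], labels[keep], switch(stat, mean = mean, sum = sum,
                                              max = max))
  ids <- as.integer(names(agg))
  nm <- if (inherits(atlas, "synthetic_atlas")) unname(atlas$names[as.character(ids)])
        else NA_character_
  data.frame(region = ids, name = nm, value = as.vector(agg),
             stringsAsFactors = FALSE)
}

#' Iterative occlusion trace
#'
#' Starting from the baseline prediction, repeatedly occludes a noise cube
#' centered on the most relevant remaining voxel, re-predicts, and zeroes the
#' occluded cube in the working relevance map so successive windows overlap
#' minimally. Predictions are on the sigmoid scale. Ties at the argmax are
#' broken toward the lowest array index; if the working map is exhausted,
#' remaining centers fall back to uniform-random brain voxels (recorded in
#' the result).
#'
#' @param model `sfcn` model used for the predictions (any mode; predictions
#'   are reported on the sigmoid scale).
#' @param volume 3D input array.
#' @param map relevance map guiding the occlusion (3D array or
#'   `relevance_map`).
#' @param iterations number of occlusion steps.
#' @param cube odd cube width (default scales with the grid; 15 at grid 48).
#' @param seed RNG seed for the injected noise (and any fallback picks).
#' @return object of class `perturbation_trace`: `trace` (length
#'   `iterations + 1`, baseline first), `centers` (iterations x 3), `fallback`
#'   (logical per iteration), `aopc`.
#' @export
occlusion_trace <- function(model, volume, map, iterations = 20, cube = NULL,
                            seed = 1) {
  if (is.null(cube)) cube <- default_cube(dim(volume)[1])
  stopifnot(is_odd(cube), iterations >= 0)
  work <- map_values(map)
  stopifnot(identical(dim(work), dim(volume)))
  to_sigmoid <- function(p) if (model$sigmoid) p else plogis(p)
  brain <- which(volume > 0)

  trace <- numeric(iterations + 1)
  centers <- matrix(NA_integer_, iterations, 3)
  fallback <- logical(iterations)
  trace[1] <- to_sigmoid(predict_volumes(model, volume))
  x <- volume
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      if (any(work > 0)) {
        center <- arrayInd(which.max(work), dim(work))[1, ]
      } else {
        fallback[it] <- TRUE
        center <- arrayInd(sample(brain, 1), dim(volume))[1, ]
      }
      centers[it, ] <- center
      x <- inject_noise_cube(x, center, cube)
      h <- (cube - 1) / 2
      lo <- pmax(center - h, 1); hi <- pmin(center + h, dim(work))
      work[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0
      trace[it + 1] <- to_sigmoid(predict_volumes(model, x))
    }
  })
  if (any(fallback))
    message(sum(fallback), " occlusion step(s) fell back to random brain voxels")
  structure(list(trace = trace, centers = centers, fallback = fallback,
                 aopc = aopc_from_trace(trace)),
            class = "perturbation_trace")
}

#' @noRd
aopc_from_trace <- function(trace) {
  if (length(trace) < 2) return(NA_real_)
  mean(trace[1] - trace[-1])
}

#' Area over the perturbation curve
#'
#' Mean drop from the baseline prediction across the occlusion iterations:
#' `AOPC = (1/n) * sum_i (y0 - y_i)`.
#'
#' @param trace a `perturbation_trace` or numeric prediction vector
#'   (baseline first, length >= 2).
#' @return AOPC value.
#' @export
aopc <- function(trace) {
  if (inherits(trace, "perturbation_trace")) trace <- trace$trace
  if (length(trace) < 2) stop("trace must contain a baseline and >= 1 iteration")
  aopc_from_trace(trace)
}

#' @export
print.perturbation_trace <- function(x, ...) {
  cat(sprintf("<perturbation_trace> %d iterations, y0=%.3f, AOPC=%.4f%s\n",
              length(x$trace) - 1, x$trace[1], x$aopc,
              if (any(x$fallback)) sprintf(" (%d fallback)", sum(x$fallback))
              else ""))
  invisible(x)
}
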