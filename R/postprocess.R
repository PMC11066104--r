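# Relevance-map postprocessing: raw maps become analysis-ready in the fixed
# order clip -> mask -> smooth. Clipping keeps only evidence in favor of the
# positive class; masking removes edge effects outside the brain; box
# smoothing (zero-padded, then re-masked by the caller if needed) raises the
# signal-to-noise ratio before dimensionality reduction.

#' @noRd
map_values <- function(map) if (inherits(map, "relevance_map")) map$values else map

#' @noRd
map_rewrap <- function(map, values) {
  if (inherits(map, "relevance_map")) {
    map$values <- values
    map
  } else values
}

#' Clip a relevance map to nonnegative values
#'
#' @param map a `relevance_map` or plain 3D array.
#' @return same type, with `r' = max(r, 0)` voxel-wise.
#' @export
clip_positive <- function(map) {
  map_rewrap(map, pmax(map_values(map), 0))
}

#' Nullify relevance outside the brain
#'
#' Enforces the masking predicate: wherever the input volume is exactly zero,
#' the relevance is set to zero.
#'
#' @param map a `relevance_map` or 3D array.
#' @param volume the input volume on the same grid (zero outside the brain).
#' @return masked map of the same type.
#' @export
mask_brain <- function(map, volume) {
  v <- map_values(map)
  if (!identical(dim(v), dim(volume)))
    stop("map and volume grids differ: ", paste(dim(v), collapse = "x"),
         " vs ", paste(dim(volume), collapse = "x"))
  v[volume == 0] <- 0
  map_rewrap(map, v)
}

#' Box-smooth a relevance map
#'
#' Convolution with a constant normalized cubic kernel (default 3x3x3),
#' zero-padded at the borders. Total relevance over interior-supported maps
#' is preserved; border truncation can only remove mass.
#'
#' @param map a `relevance_map` or 3D array.
#' @param width odd kernel width in voxels; 1 is the identity.
#' @return smoothed map of the same type.
#' @export
smooth_box <- function(map, width = 3) {
  if (!is_odd(width)) stop("smoothing width must be odd")
  map_rewrap(map, box_blur3d(map_values(map), width))
}

#' Rescale a map to the unit interval for display
#'
#' Affine rescaling to min 0 / max 1; ordering of voxels is preserved. A
#' constant map cannot be rescaled and returns zeros with a warning.
#'
#' @param map a `relevance_map` or 3D array.
#' @return rescaled map of the same type.
#' @export
normalize_display <- function(map) {
  v <- map_values(map)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant map cannot be normalized; returning zeros")
    return(map_rewrap(map, v * 0))
  }
  map_rewrap(map, (v - rng[1]) / (rng[2] - rng[1]))
}

#' Standard analysis-ready postprocessing
#'
#' Applies the fixed pipeline clip -> mask (-> smooth when `smooth > 1`,
#' followed by re-masking so smoothing cannot bleed relevance outside the
#' brain).
#'
#' @param map a `relevance_map` or 3D array.
#' @param volume matching input volume.
#' @param smooth odd box width, or 1 to skip smoothing (smoothing is only
#'   required before principal-component compression).
#' @return postprocessed map of the same type.
#' @export
postprocess_map <- function(map, volume, smooth = 1) {
  out <- mask_brain(clip_positive(map), volume)
  if (smooth > 1) out <- mask_brain(smooth_box(out, smooth), volume)
  out
}
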