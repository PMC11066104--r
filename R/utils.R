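#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a distinct 31-bit child seed from a base seed and a stream label.
#' @noRd
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + s * 1009 + 12345) %% 2147483647)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank handling of ties.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Binary classification metrics at a fixed threshold.
#' @noRd
binary_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(auc = auc_score(labels, scores),
    balanced_accuracy = mean(c(sens, spec)),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = sens,
    specificity = spec)
}

#' @noRd
is_odd <- function(x) x %% 2 == 1

# 3D box blur with an odd cubic kernel; zero-padded borders. Used both by the
# reference-map generator and the relevance-map smoothing stage.
#' @noRd
box_blur3d <- function(arr, width) {
  stopifnot(length(dim(arr)) == 3, is_odd(width), width >= 1)
  if (width == 1) return(arr)
  d <- dim(arr)
  x <- array(arr, c(d, 1L, 1L))
  w <- array(1 / width^3, c(width, width, width, 1L, 1L))
  array(.conv3d_fwd(x, w, 0), d)
}
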