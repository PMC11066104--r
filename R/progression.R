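# Progression targets, relevance-map compression, and the nested
# cross-validated model-comparison suite.
#
# For a subject with last MCI visit t_neg and first dementia visit t_pos
# (infinite when absent), the horizon-gamma target at visit t is
#   z = 1  if t + gamma >= t_pos,
#   z = 0  if t + gamma <= t_neg,
#   z = NA otherwise (status at t + gamma unknown; excluded from modeling).

DAYS_PER_YEAR <- 365.25

#' Construct progression targets from a visit table
#'
#' One record per (subject, pre-dementia visit, horizon). Ambiguous
#' trajectories must be excluded beforehand (see [classify_trajectory()]);
#' rows from ambiguous subjects are rejected.
#'
#' @param visits data.frame with `subject_id`, `visit_date` (days),
#'   `diagnosis`.
#' @param horizons horizons in years (default 1:5).
#' @return data.frame: `subject_id`, `visit_date`, `horizon`, `z` (1, 0, or
#'   NA), `t_neg`, `t_pos` (days; `t_pos` is `Inf` for never-progressing
#'   subjects).
#' @export
build_targets <- function(visits, horizons = 1:5) {
  split_v <- split(visits, visits$subject_id)
  cls <- vapply(split_v, function(d) classify_trajectory(d$diagnosis), "")
  if (any(cls == "ambiguous"))
    stop("ambiguous trajectories must be excluded before target construction: ",
         paste(head(names(split_v)[cls == "ambiguous"], 5), collapse = ", "))
  rows <- lapply(split_v, function(d) {
    t_neg <- suppressWarnings(max(d$visit_date[d$diagnosis == "MCI"]))
    if (!is.finite(t_neg)) return(NULL)
    dem <- d$visit_date[d$diagnosis == "DEM"]
    t_pos <- if (length(dem)) min(dem) else Inf
    tp <- d$visit_date[d$visit_date < t_pos]      # pre-diagnosis timepoints
    if (!length(tp)) return(NULL)
    expand <- expand.grid(visit_date = tp, horizon = horizons)
    gd <- expand$horizon * DAYS_PER_YEAR
    z <- ifelse(expand$visit_date + gd >= t_pos, 1L,
                ifelse(expand$visit_date + gd <= t_neg, 0L, NA_integer_))
    data.frame(subject_id = d$subject_id[1], expand, z = z,
               t_neg = t_neg, t_pos = t_pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Principal-component compression of relevance maps
#'
#' Fits a PCA basis on vectorized (smoothed) relevance maps and returns the
#' per-map loadings. The default retains 64 components; requesting more
#' components than the achievable rank (`n_maps - 1`) is rejected, so small
#' fixtures should pass `k = min(64, n_maps - 1)`.
#'
#' @param maps list of 3D arrays (or `relevance_map`s), one per subject, or a
#'   matrix with one row per map.
#' @param k number of components to retain.
#' @return object of class `map_pca`: `rotation` (voxels x k), `center`,
#'   `sdev`, `loadings` (n x k), `explained_variance` (fraction per
#'   component).
#' @export
fit_map_pca <- function(maps, k = 64) {
  x <- if (is.matrix(maps)) maps
       else do.call(rbind, lapply(maps, function(m) as.vector(map_values(m))))
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (k > max_rank)
    stop("k = ", k, " exceeds the achievable rank ", max_rank,
         " for ", nrow(x), " maps")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(rotation = pc$rotation, center = pc$center,
                 sdev = pc$sdev[seq_len(k)],
                 loadings = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)]),
            class = "map_pca")
}

#' Project maps onto a fitted PCA basis
#' @param pca a `map_pca`.
#' @param maps list of maps or a matrix (rows = maps).
#' @return n x k loading matrix.
#' @export
project_maps <- function(pca, maps) {
  x <- if (is.matrix(maps)) maps
       else do.call(rbind, lapply(maps, function(m) as.vector(map_values(m))))
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' Reconstruct maps from loadings
#' @param pca a `map_pca`.
#' @param loadings n x k matrix.
#' @return n x voxels matrix.
#' @export
reconstruct_maps <- function(pca, loadings) {
  sweep(loadings %*% t(pca$rotation), 2, pca$center, `+`)
}

#' Stratified subject-level folds
#'
#' Thin wrapper over [make_subject_folds()] stratifying on outcome, sex and
#' 10-year age bins.
#'
#' @param subject_id per-row subject ids.
#' @param z per-row binary outcome.
#' @param sex per-row sex.
#' @param age per-row age in years.
#' @param k folds.
#' @param seed RNG seed.
#' @return integer fold per row (all rows of a subject share a fold).
#' @export
stratified_subject_folds <- function(subject_id, z, sex, age, k = 5, seed = 1) {
  make_subject_folds(subject_id,
                     data.frame(z = z, sex = sex, age = age), k, seed)
}

#' @noRd
suite_design <- function(df, model = c("base", "pred", "comp")) {
  model <- match.arg(model)
  sexm <- as.integer(df$sex == "M")
  x <- cbind(age = df$age, sex = sexm, age_sex = df$age * sexm)
  if (model %in% c("pred", "comp"))
    x <- cbind(x, yhat = df$yhat, age_yhat = df$age * df$yhat)
  if (model == "comp") {
    comps <- as.matrix(df[grep("^c[0-9]+$", names(df))])
    x <- cbind(x, comps)
  }
  x
}

#' Nested cross-validated model-comparison suite
#'
#' For each horizon, fits three l1-penalized logistic models of the
#' progression target: a covariate baseline (age, sex, age x sex), the
#' baseline plus the classifier prediction (and its age interaction), and
#' that model plus the map component vector. The regularization strength is
#' tuned on inner subject-level folds only; evaluation uses one seeded random
#' timepoint per test subject, shared across the three models so comparisons
#' are paired. Models are compared fold-wise with one-sided signed-rank
#' tests.
#'
#' @param targets output of [build_targets()].
#' @param features data.frame keyed by (`subject_id`, `visit_date`) with
#'   `age`, `sex`, `yhat`, and component columns `c1`, `c2`, ... (the
#'   component columns may be absent, in which case the component model is
#'   skipped).
#' @param horizons subset of horizons to evaluate (default: all in
#'   `targets`).
#' @param k outer folds.
#' @param inner_k inner folds for lambda tuning.
#' @param seed RNG seed (folds and test-timepoint draws).
#' @return list with `metrics` (data.frame: horizon, model, fold, auc,
#'   balanced_accuracy, ppv, sensitivity, specificity), `comparisons`
#'   (signed-rank p-values per horizon), and `predictions`.
#' @export
run_model_suite <- function(targets, features, horizons = NULL, k = 5,
                            inner_k = 5, seed = 1) {
  horizons <- horizons %||% sort(unique(targets$horizon))
  have_comps <- length(grep("^c[0-9]+$", names(features))) > 0
  models <- if (have_comps) c("base", "pred", "comp") else c("base", "pred")
  df_all <- merge(targets, features, by = c("subject_id", "visit_date"))

  metrics <- list(); preds_out <- list(); comparisons <- list()
  for (h in horizons) {
    df <- df_all[df_all$horizon == h & !is.na(df_all$z), ]
    if (!nrow(df)) next
    subj_z <- tapply(df$z, df$subject_id, max)
    fold <- stratified_subject_folds(
      df$subject_id, subj_z[df$subject_id],
      df$sex, df$age, k, seed = child_seed(seed, paste0("fold", h)))

    # one seeded random test timepoint per subject, shared across models
    test_rows <- with_seed(child_seed(seed, paste0("tp", h)), {
      unlist(lapply(split(seq_len(nrow(df)), df$subject_id),
                    function(ix) ix[sample.int(length(ix), 1)]))
    })
    is_test_row <- seq_len(nrow(df)) %in% test_rows

    for (mdl in models) {
      x <- suite_design(df, mdl)
      for (f in seq_len(k)) {
        tr <- fold != f
        te <- (!tr) & is_test_row
        if (length(unique(df$z[tr])) < 2 || length(unique(df$z[te])) < 2) {
          metrics[[length(metrics) + 1L]] <- data.frame(
            horizon = h, model = mdl, fold = f, auc = NA_real_,
            balanced_accuracy = NA_real_, ppv = NA_real_,
            sensitivity = NA_real_, specificity = NA_real_)
          next
        }
        inner_fold <- make_subject_folds(
          df$subject_id[tr], data.frame(z = df$z[tr]), inner_k,
          seed = child_seed(seed, paste0("inner", h, f)))
        # glmnet warns on small inner-fold classes; degenerate folds are
        # handled explicitly above, so the warnings are noise here
        cv <- suppressWarnings(
          glmnet::cv.glmnet(x[tr, , drop = FALSE], df$z[tr],
                            family = "binomial", alpha = 1,
                            foldid = inner_fold, nfolds = inner_k))
        ph <- as.vector(predict(cv, x[te, , drop = FALSE],
                                s = "lambda.min", type = "response"))
        mm <- binary_metrics(df$z[te], ph)
        metrics[[length(metrics) + 1L]] <- data.frame(
          horizon = h, model = mdl, fold = f, t(mm))
        preds_out[[length(preds_out) + 1L]] <- data.frame(
          horizon = h, model = mdl, fold = f,
          subject_id = df$subject_id[te], visit_date = df$visit_date[te],
          z = df$z[te], p = ph, stringsAsFactors = FALSE)
      }
    }
    met_h <- do.call(rbind, metrics)
    auc_of <- function(mdl) {
      m <- met_h[met_h$horizon == h & met_h$model == mdl, ]
      m$auc[order(m$fold)]
    }
    cmp <- list(horizon = h)
    if (all(c("base", "pred") %in% models))
      cmp$pred_vs_base <- signed_rank_p(auc_of("pred"), auc_of("base"))
    if (all(c("pred", "comp") %in% models))
      cmp$comp_vs_pred <- signed_rank_p(auc_of("comp"), auc_of("pred"))
    comparisons[[length(comparisons) + 1L]] <- as.data.frame(cmp)
  }
  list(metrics = do.call(rbind, metrics),
       comparisons = do.call(rbind, comparisons),
       predictions = do.call(rbind, preds_out))
}

# One-sided paired Wilcoxon signed-rank p-value for "a > b".
#' @noRd
signed_rank_p <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE,
                               alternative = "greater")$p.value)
}

#' Assemble a subject's morphological record
#'
#' The longitudinal bundle backing individual-level reporting: the dated
#' prediction series with map references, the annualized change in prediction
#' computed from the first two visits, and per-horizon progression
#' probabilities.
#'
#' @param subject_id subject identifier.
#' @param visits data.frame with `visit_date` (days) and `yhat`, optionally
#'   `map_path`.
#' @param progression optional data.frame with `horizon` and `p`
#'   (probabilities from [run_model_suite()]).
#' @return object of class `morphological_record`; serializes losslessly via
#'   [record_to_json()] / [record_from_json()].
#' @export
morphological_record <- function(subject_id, visits, progression = NULL) {
  stopifnot(nrow(visits) >= 1)
  visits <- visits[order(visits$visit_date), , drop = FALSE]
  slope <- if (nrow(visits) >= 2) {
    dy <- visits$yhat[2] - visits$yhat[1]
    dt <- (visits$visit_date[2] - visits$visit_date[1]) / DAYS_PER_YEAR
    dy / dt
  } else NA_real_
  structure(list(subject_id = subject_id,
                 visits = visits,
                 slope_per_year = slope,
                 progression = progression),
            class = "morphological_record")
}

#' @rdname morphological_record
#' @param record a `morphological_record`.
#' @param path optional output path.
#' @export
record_to_json <- function(record, path = NULL) {
  txt <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, digits = NA,
                          na = "null")
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' @rdname morphological_record
#' @param json JSON text or file path from [record_to_json()].
#' @export
record_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  rec <- morphological_record(x$subject_id, as.data.frame(x$visits),
                              if (!is.null(x$progression))
                                as.data.frame(x$progression))
  rec
}

#' @export
print.morphological_record <- function(x, ...) {
  cat(sprintf("<morphological_record %s> %d visits, slope %s/yr\n",
              x$subject_id, nrow(x$visits),
              if (is.na(x$slope_per_year)) "NA"
              else sprintf("%.3f", x$slope_per_year)))
  invisible(x)
}
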