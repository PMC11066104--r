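# End-to-end phantom studies. These drivers reproduce the package's headline
# property checks from scratch — generate a cohort, train, explain, validate —
# and back both the acceptance test suite and scripts/acceptance.R. They are
# deliberately deterministic given `seed`.

#' Pick the atlas region whose size is closest to a target brain fraction
#' @param atlas a [synthetic_atlas()].
#' @param fraction target fraction of brain volume.
#' @param rank 1 for the closest region, 2 for the runner-up, ...
#' @return integer region id.
#' @export
region_near_fraction <- function(atlas, fraction = 0.05, rank = 1) {
  sizes <- table(atlas$labels[atlas$labels > 0])
  target <- fraction * sum(atlas$brain_mask)
  as.integer(names(sizes)[order(abs(sizes - target))][rank])
}

#' Full relevance-map validation study on a phantom cohort
#'
#' Generates a lesioned phantom cohort (one focal lesion region of roughly 5%
#' brain volume, plus an independent sex-linked region for the
#' alternative-task null), trains the classifier and a sex classifier with
#' subject-disjoint cross-validation, produces composite-LRP maps for all
#' true positives, and runs the validation battery: localization, the three
#' null pipelines, occlusion/AOPC, and Dice/nCC against a reference map built
#' from the true lesion region.
#'
#' Scale defaults (grid 32, 2 folds, 40 epochs with a stepwise learning-rate
#' schedule, 3 blocks) keep the full study within roughly ten CPU-minutes;
#' they shrink the full-scale setting without changing its structure. The
#' schedule matters: at constant rates the loss plateaus at desk scale.
#'
#' @param seed master seed; all randomness derives from it.
#' @param grid,n_regions,n_per_class,effect,noise_sd cohort parameters.
#' @param folds,epochs,lr,blocks,base_channels training parameters.
#' @param occl_stride occlusion runs on every `occl_stride`-th true positive.
#' @param iterations occlusion iterations.
#' @return list of study results (see the acceptance tests for the fields).
#' @export
phantom_validation_study <- function(seed = 1, grid = 32, n_regions = 12,
                                     n_per_class = 100, effect = 0.3,
                                     noise_sd = 0.05, folds = 2, epochs = 40,
                                     lr = c(rep(1, 12), rep(0.3, 14),
                                            rep(0.1, 14)),
                                     blocks = 3, base_channels = 4,
                                     occl_stride = 4, iterations = 20) {
  atlas <- synthetic_atlas(grid = grid, n_regions = n_regions,
                           seed = child_seed(seed, "atlas"))
  lesion_region <- region_near_fraction(atlas, 0.05, rank = 1)
  sex_region <- region_near_fraction(atlas, 0.05, rank = 2)
  cohort <- generate_cohort(n_per_class, atlas,
                            lesion_regions = lesion_region, effect = effect,
                            noise_sd = noise_sd, sex_regions = sex_region,
                            sex_effect = effect,
                            seed = child_seed(seed, "cohort"))

  fit <- train_classifier(cohort, folds = folds, epochs = epochs, lr = lr,
                          blocks = blocks, base_channels = base_channels,
                          seed = child_seed(seed, "task"))
  pr <- fit$predictions
  auc_task <- auc_score(pr$label, pr$yhat)

  fit_sex <- train_classifier(cohort, folds = folds, epochs = epochs, lr = lr,
                              blocks = blocks, base_channels = base_channels,
                              label_field = "sex",
                              seed = child_seed(seed, "sex"))
  psex <- fit_sex$predictions
  auc_sex <- auc_score(psex$label, psex$yhat)
  auc_sex_on_lesion <- auc_score(pr$label, psex$yhat)

  models <- lapply(fit$models, function(m) strip_sigmoid(fuse_batchnorm(m)))
  sex_models <- lapply(fit_sex$models,
                       function(m) strip_sigmoid(fuse_batchnorm(m)))

  # out-of-sample composite maps for all true positives
  tp <- which(pr$label == 1 & pr$yhat > 0.5)
  task_post <- lapply(tp, function(i) {
    ex <- explain(models[[pr$fold[i]]], cohort[[i]]$volume)
    postprocess_map(ex, cohort[[i]]$volume)
  })

  lesion <- atlas$labels == lesion_region
  lesion_fraction <- sum(lesion) / sum(atlas$brain_mask)
  rel_frac <- vapply(task_post, function(m) {
    s <- sum(m$values)
    if (s <= 0) return(NA_real_)
    sum(m$values[lesion]) / s
  }, 0)
  relevance_fraction <- mean(rel_frac, na.rm = TRUE)

  # null-pipeline maps for every true positive (averages over all TPs, like
  # the task pipeline); occlusion below runs on a strided subset for time
  vols <- lapply(tp, function(i) cohort[[i]]$volume)
  allvols <- lapply(cohort, `[[`, "volume")
  post_all <- function(maps) lapply(seq_along(tp), function(j)
    postprocess_map(maps[[j]], vols[[j]]))

  rw_post <- post_all(null_pipeline_maps(
    "random_weights", models[[1]], vols, seed = child_seed(seed, "rw"),
    blocks = blocks, base_channels = base_channels))
  # scrambling statistics from the full (case + control) cohort
  ri_post <- post_all(null_pipeline_maps(
    "random_images", models[[1]], allvols,
    seed = child_seed(seed, "ri"))[seq_along(tp)])
  at_post <- post_all(lapply(seq_along(tp), function(j)
    explain(sex_models[[pr$fold[tp[j]]]], vols[[j]])))

  sub <- seq(1, length(tp), by = occl_stride)
  cube <- default_cube(grid)
  aopc_of <- function(maps) vapply(sub, function(j)
    suppressMessages(occlusion_trace(
      fit$models[[pr$fold[tp[j]]]], vols[[j]], maps[[j]],
      iterations = iterations, cube = cube,
      seed = child_seed(seed, paste0("occ", j))))$aopc, 0)
  aopc_means <- c(task = mean(aopc_of(task_post)),
                  random_weights = mean(aopc_of(rw_post)),
                  random_images = mean(aopc_of(ri_post)),
                  alt_task = mean(aopc_of(at_post)))

  G <- generate_reference_map(atlas, hot_regions = lesion_region, blur = 3)
  avg <- function(maps)
    Reduce(`+`, lapply(maps, function(m) m$values)) / length(maps)
  avg_task <- avg(task_post)
  avgs <- list(task = avg_task, random_weights = avg(rw_post),
               random_images = avg(ri_post), alt_task = avg(at_post))
  nccs <- vapply(avgs, ncc, 0, b = G)
  curves <- lapply(avgs, dice_curve, reference = G)

  list(seed = seed, atlas = atlas, lesion_region = lesion_region,
       sex_region = sex_region, cohort = cohort, fit = fit,
       fit_sex = fit_sex, models = models, sex_models = sex_models,
       tp = tp, occl_subset = tp[sub], task_maps = task_post,
       auc_task = auc_task, auc_sex = auc_sex,
       auc_sex_on_lesion = auc_sex_on_lesion,
       lesion_fraction = lesion_fraction,
       relevance_fraction = relevance_fraction,
       localization_ratio = relevance_fraction / lesion_fraction,
       aopc = aopc_means, ncc = nccs, dice_curves = curves,
       reference_map = G)
}

#' Progression model-suite sanity study
#'
#' Generates a longitudinal visit table with covariates independent of the
#' outcome, then runs the nested cross-validated suite twice: once with a
#' pure-noise classifier prediction (all models should hover at chance) and
#' once with a prediction that perfectly separates the target (the
#' prediction-bearing model should reach AUC 1).
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param horizons horizons (years) to evaluate; defaults to 1-3, the range
#'   with two-class support under the visit grammar's typical 2-5 years of
#'   follow-up (horizon-5 negatives require longer observation than the
#'   generator produces).
#' @param k outer folds.
#' @return list with `null` and `separating` suite outputs, mean AUCs, and a
#'   leakage audit flag.
#' @export
progression_study <- function(seed = 1, n_subjects = 300,
                              horizons = c(1, 2, 3), k = 5) {
  vt <- generate_visit_table(n_subjects, seed = child_seed(seed, "visits"))
  vt <- vt[vt$trajectory != "ambiguous", ]
  tg <- build_targets(vt, horizons = horizons)

  subs <- unique(vt$subject_id)
  meta <- with_seed(child_seed(seed, "meta"), data.frame(
    subject_id = subs,
    age = runif(length(subs), 55, 90),
    sex = sample(c("F", "M"), length(subs), TRUE),
    stringsAsFactors = FALSE))
  feats <- merge(unique(tg[c("subject_id", "visit_date")]), meta,
                 by = "subject_id")

  feats_null <- feats
  feats_null$yhat <- with_seed(child_seed(seed, "noise"),
                               runif(nrow(feats)))
  out_null <- run_model_suite(tg, feats_null, horizons = horizons, k = k,
                              seed = child_seed(seed, "suite0"))

  # per-horizon perfectly separating prediction: yhat = z
  sep_auc <- c()
  for (h in horizons) {
    zh <- tg[tg$horizon == h, c("subject_id", "visit_date", "z")]
    fh <- merge(feats, zh, by = c("subject_id", "visit_date"))
    fh$yhat <- ifelse(is.na(fh$z), 0.5, fh$z)
    fh$z <- NULL
    oh <- run_model_suite(tg, fh, horizons = h, k = k,
                          seed = child_seed(seed, paste0("sep", h)))
    m <- oh$metrics
    sep_auc <- c(sep_auc, mean(m$auc[m$model == "pred"], na.rm = TRUE))
  }

  m0 <- out_null$metrics
  base_auc <- mean(m0$auc[m0$model == "base"], na.rm = TRUE)

  # leakage audit over the null run
  leak_free <- TRUE
  pr <- out_null$predictions
  for (h in unique(pr$horizon)) {
    sub_pr <- pr[pr$horizon == h & pr$model == "base", ]
    byfold <- split(sub_pr$subject_id, sub_pr$fold)
    for (f in names(byfold))
      if (length(intersect(byfold[[f]],
                           unlist(byfold[setdiff(names(byfold), f)]))))
        leak_free <- FALSE
  }

  list(null = out_null, base_auc_null = base_auc,
       pred_auc_separating = mean(sep_auc), leak_free = leak_free,
       horizons = horizons)
}
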