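# Cross-validated training of the phantom classifier: subject-disjoint
# stratified folds, vanilla SGD on binary cross-entropy, lowest-validation-
# loss epoch selection, and optional random-box augmentation (the same
# noise-cube injection later used by the occlusion analysis, so the model is
# approximately invariant to it).

#' Subject-disjoint stratified fold assignment
#'
#' Subjects are stratified on the supplied categorical/binned variables and
#' dealt round-robin into `k` folds, so all rows (timepoints) of a subject
#' share a fold and per-fold stratum proportions stay close to global ones.
#'
#' @param subject_id character vector, one entry per row.
#' @param strata data.frame (or list) of per-row stratification variables;
#'   numeric columns are binned into 10-unit bins (used for age).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold (1..k) per row, named by subject for the unique
#'   subjects in attribute `"subject_fold"`.
#' @export
make_subject_folds <- function(subject_id, strata, k, seed = 1) {
  stopifnot(k >= 1)
  sdf <- as.data.frame(strata, stringsAsFactors = FALSE)
  first <- !duplicated(subject_id)
  subs <- subject_id[first]
  sdf <- sdf[first, , drop = FALSE]
  for (j in seq_along(sdf))
    if (is.numeric(sdf[[j]]) && length(unique(sdf[[j]])) > 5)
      sdf[[j]] <- floor(sdf[[j]] / 10)    # 10-unit bins for continuous vars
  key <- do.call(paste, c(sdf, sep = "|"))
  fold_of <- integer(length(subs))
  counter <- 0L
  with_seed(seed, {
    for (g in split(seq_along(subs), key)) {
      g <- g[sample.int(length(g))]
      fold_of[g] <- (counter + seq_along(g) - 1L) %% k + 1L
      counter <- counter + length(g)
    }
  })
  names(fold_of) <- subs
  out <- fold_of[subject_id]
  attr(out, "subject_fold") <- fold_of
  out
}

# Default occlusion/augmentation cube width: ~9% of the side length (the
# ratio of a 15-voxel cube to a ~167-voxel full-resolution grid), rounded to
# an odd width of at least 3.
#' @noRd
default_cube <- function(grid) {
  w <- round(grid * 0.09)
  max(3L, as.integer(if (w %% 2 == 0) w + 1 else w))
}

# Inject a cube of U(0,1) noise centered at `center`, clipped at borders.
#' @noRd
inject_noise_cube <- function(vol, center, width) {
  h <- (width - 1) / 2
  d <- dim(vol)
  lo <- pmax(center - h, 1)
  hi <- pmin(center + h, d)
  n <- prod(hi - lo + 1)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- runif(n)
  vol
}

#' @noRd
random_box_augment <- function(vol, width, prob, boxes = 2L) {
  support <- NULL
  for (b in seq_len(boxes)) {
    if (runif(1) >= prob) next
    if (is.null(support)) {
      support <- which(vol > 0)
      if (!length(support)) return(vol)
    }
    center <- arrayInd(sample(support, 1), dim(vol))[1, ]
    vol <- inject_noise_cube(vol, center, width)
  }
  vol
}

#' @noRd
bce_loss <- function(y, yhat) {
  eps <- 1e-12
  -mean(y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))
}

# One SGD epoch over (volumes, labels); returns the updated model.
#' @noRd
train_epoch <- function(model, volumes, labels, batch, lr,
                        augment, cube, augment_prob, augment_boxes = 2L) {
  ord <- sample.int(length(volumes))
  for (ii in split(ord, ceiling(seq_along(ord) / batch))) {
    vols <- volumes[ii]
    if (augment)
      vols <- lapply(vols, random_box_augment, width = cube,
                     prob = augment_prob, boxes = augment_boxes)
    x <- stack_volumes(vols)
    fw <- model_forward(model, x, training = TRUE, record = FALSE)
    model <- fw$model                       # running batchnorm stats
    dlogit <- (fw$yhat - labels[ii]) / length(ii)
    grads <- model_backward(model, fw, dlogit)
    model <- sgd_update(model, grads, lr)
  }
  model
}

#' Train the classifier with subject-disjoint cross-validation
#'
#' For each fold, the model is trained from a fresh initialization on the
#' remaining folds (with an inner subject-level validation split used only to
#' select the epoch with the lowest validation loss) and produces
#' out-of-sample sigmoid predictions for the held-out fold.
#'
#' @param cohort list of phantoms from [generate_cohort()].
#' @param folds either an integer number of folds or a precomputed integer
#'   fold vector (one entry per phantom; subject-disjoint).
#' @param epochs SGD epochs per fold (0 returns initialized models).
#' @param batch mini-batch size.
#' @param lr SGD learning rate; a vector gives a per-epoch (stepwise)
#'   schedule, with the last value reused for any remaining epochs.
#' @param val_frac fraction of training subjects held out for epoch selection.
#' @param augment enable random-box noise augmentation.
#' @param augment_prob per-box probability of injecting a noise cube.
#' @param augment_boxes number of independent box-injection attempts per
#'   training volume and epoch.
#' @param cube odd cube width for augmentation (default scales with grid).
#' @param max_restarts extra seeded initializations to try when the best
#'   validation loss stays above `restart_threshold` (multi-start SGD).
#' @param restart_threshold validation BCE below which a fold counts as
#'   converged and no restart happens.
#' @param label_field phantom field used as the training label (`"label"` for
#'   the lesion task; `"sex"` trains the orthogonal-attribute null model).
#' @param seed RNG seed.
#' @param ... passed to [build_model()] (e.g. `blocks`, `base_channels`).
#' @return list with `models` (per-fold trained models, in sigmoid mode),
#'   `predictions` (data.frame: subject_id, fold, label, yhat, out-of-sample),
#'   `folds` (fold vector), and `history` (per-fold epoch losses).
#' @export
train_classifier <- function(cohort, folds = 5, epochs = 30, batch = 8,
                             lr = 1, val_frac = 0.2, augment = TRUE,
                             augment_prob = 0.7, augment_boxes = 2L,
                             cube = NULL, max_restarts = 2,
                             restart_threshold = 0.45,
                             label_field = "label", seed = 1, ...) {
  stopifnot(length(cohort) >= 2)
  meta <- cohort_metadata(cohort)
  labels <- if (label_field == "label") meta$label
            else as.integer(meta[[label_field]] == sort(unique(meta[[label_field]]))[1])
  grid <- dim(cohort[[1]]$volume)[1]
  if (is.null(cube)) cube <- default_cube(grid)

  if (length(folds) == 1L) {
    k <- as.integer(folds)
    fold_vec <- make_subject_folds(
      meta$subject_id,
      data.frame(label = labels, site = meta$site, sex = meta$sex,
                 age = meta$age),
      k, seed = child_seed(seed, "folds"))
  } else {
    fold_vec <- as.integer(folds)
    stopifnot(length(fold_vec) == length(cohort))
    k <- max(fold_vec)
    leak <- tapply(fold_vec, meta$subject_id, function(f) length(unique(f)))
    if (any(leak > 1))
      stop("subject leakage across folds: ",
           paste(names(leak)[leak > 1], collapse = ", "))
  }

  volumes <- lapply(cohort, `[[`, "volume")
  models <- vector("list", k)
  history <- vector("list", k)
  preds <- rep(NA_real_, length(cohort))

  for (f in seq_len(k)) {
    test_idx <- which(fold_vec == f)
    train_idx <- which(fold_vec != f)
    model <- build_model(grid = grid, seed = child_seed(seed, paste0("init", f)),
                         ...)
    if (epochs > 0) {
      # subject-level validation split inside the training folds
      tr_subs <- unique(meta$subject_id[train_idx])
      nval <- max(1L, round(val_frac * length(tr_subs)))
      val_subs <- with_seed(child_seed(seed, paste0("val", f)),
                            sample(tr_subs, nval))
      fit_idx <- train_idx[!(meta$subject_id[train_idx] %in% val_subs)]
      val_idx <- train_idx[meta$subject_id[train_idx] %in% val_subs]
      if (!length(fit_idx)) fit_idx <- train_idx
      if (!length(val_idx)) val_idx <- train_idx

      # multi-start: SGD from random init can plateau at desk scale; retry
      # from a fresh seeded init when the best validation loss stays poor
      best <- list(loss = Inf, model = model)
      losses <- NULL
      for (attempt in 0:max_restarts) {
        if (attempt > 0) {
          if (best$loss <= restart_threshold) break
          message("fold ", f, ": validation loss ", round(best$loss, 3),
                  " after attempt ", attempt, "; restarting from new init")
          model <- build_model(grid = grid,
                               seed = child_seed(seed,
                                                 paste0("init", f, "r", attempt)),
                               ...)
        }
        att_losses <- numeric(epochs)
        with_seed(child_seed(seed, paste0("sgd", f, "r", attempt)), {
          for (ep in seq_len(epochs)) {
            lr_ep <- lr[min(ep, length(lr))]
            model <- train_epoch(model, volumes[fit_idx], labels[fit_idx],
                                 batch, lr_ep, augment, cube, augment_prob,
                                 augment_boxes)
            model <- refresh_batchnorm_stats(model, volumes[fit_idx], batch)
            vloss <- bce_loss(labels[val_idx],
                              predict_volumes(model, volumes[val_idx], batch))
            att_losses[ep] <- vloss
            if (vloss < best$loss) best <- list(loss = vloss, model = model)
          }
        })
        losses <- c(losses, att_losses)
      }
      model <- best$model
      history[[f]] <- losses
      model$trained <- TRUE
    }
    model$fold_id <- f
    models[[f]] <- model
    preds[test_idx] <- predict_volumes(model, volumes[test_idx], batch)
  }

  list(models = models,
       predictions = data.frame(subject_id = meta$subject_id,
                                fold = fold_vec, label = labels,
                                yhat = preds, stringsAsFactors = FALSE),
       folds = fold_vec,
       history = history)
}
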