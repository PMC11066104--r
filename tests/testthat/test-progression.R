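test_that("progression targets reproduce the hand-derived trichotomy", {
  yr <- 365.25
  visits <- rbind(
    # stable: last MCI at year 6, probe t = year 2, gamma = 3 -> 0
    data.frame(subject_id = "stable", visit_date = round(c(0, 2, 4, 6) * yr),
               diagnosis = "MCI"),
    # progressive with t_pos at year 2: t = 0, gamma = 2 -> 1
    data.frame(subject_id = "fast", visit_date = round(c(0, 1, 2) * yr),
               diagnosis = c("MCI", "MCI", "DEM")),
    # gap case: t_neg year 1, t_pos year 4, t = 0, gamma = 2 -> NA
    data.frame(subject_id = "gap", visit_date = round(c(0, 1, 4) * yr),
               diagnosis = c("MCI", "MCI", "DEM")))
  tg <- build_targets(visits, horizons = c(2, 3))

  pick <- function(id, t, h)
    tg$z[tg$subject_id == id & tg$visit_date == round(t * yr) & tg$horizon == h]
  expect_identical(pick("stable", 2, 3), 0L)
  expect_identical(pick("fast", 0, 2), 1L)
  expect_identical(pick("gap", 0, 2), NA_integer_)
  # stable subjects can never be positive
  expect_true(all(tg$z[tg$subject_id == "stable"] %in% c(0L, NA_integer_)))
  # no timepoints at or after the dementia visit
  expect_true(all(tg$visit_date[tg$subject_id == "fast"] < round(2 * yr)))

  amb <- data.frame(subject_id = "x", visit_date = c(0, 300, 600),
                    diagnosis = c("MCI", "DEM", "MCI"))
  expect_error(build_targets(amb), "ambiguous")
})

test_that("trichotomy matches a brute-force re-derivation on random tables", {
  vt <- generate_visit_table(300, seed = 90)
  vt <- vt[vt$trajectory != "ambiguous", ]
  tg <- build_targets(vt, horizons = 1:5)
  yr <- 365.25

  # exactly one of {1, 0, NA} per row, re-derived independently per row
  for (i in sample(nrow(tg), 2000, replace = TRUE)) {
    row <- tg[i, ]
    d <- vt[vt$subject_id == row$subject_id, ]
    t_neg <- max(d$visit_date[d$diagnosis == "MCI"])
    dem <- d$visit_date[d$diagnosis == "DEM"]
    t_pos <- if (length(dem)) min(dem) else Inf
    expected <- if (row$visit_date + row$horizon * yr >= t_pos) 1L
                else if (row$visit_date + row$horizon * yr <= t_neg) 0L
                else NA_integer_
    expect_identical(row$z, expected)
  }
  # subjects without a dementia visit are never positive
  nodem <- !(tg$subject_id %in% vt$subject_id[vt$diagnosis == "DEM"])
  expect_false(any(tg$z[nodem] == 1L, na.rm = TRUE))
})

test_that("map PCA satisfies its spectral identities", {
  set.seed(91)
  n <- 12; v <- 200
  x <- matrix(rnorm(n * v), n, v)
  expect_error(fit_map_pca(x, k = 50), "rank")

  pc <- fit_map_pca(x, k = n - 1)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-10)
  # loading variance equals the eigenvalue, axis by axis
  expect_equal(apply(pc$loadings, 2, var), pc$sdev^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  # full-rank reconstruction recovers the data
  rec <- reconstruct_maps(pc, pc$loadings)
  expect_lt(max(abs(rec - x)), 1e-6)
  # projection of the training maps reproduces the loadings
  expect_equal(project_maps(pc, x), pc$loadings, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("stratified subject folds respect size and class counting", {
  expect_true(all(stratified_subject_folds(letters[1:7], rep(0, 7),
                                           rep("F", 7), rep(60, 7),
                                           k = 1) == 1))
  two <- stratified_subject_folds(c("a", "b"), c(0, 1), c("F", "M"),
                                  c(60, 70), k = 2)
  expect_setequal(as.vector(two), 1:2)

  set.seed(92)
  n <- 100
  z <- rep(c(1, 0), c(60, 40))
  f <- stratified_subject_folds(sprintf("s%03d", 1:n), z,
                                sample(c("F", "M"), n, TRUE),
                                runif(n, 55, 90), k = 5, seed = 4)
  pos <- tapply(z, f, sum)
  expect_true(all(abs(pos - 12) <= 2))
})

test_that("the model suite separates, nulls out, and never leaks subjects", {
  set.seed(93)
  vt <- generate_visit_table(120, seed = 94)
  vt <- vt[vt$trajectory != "ambiguous", ]
  tg <- build_targets(vt, horizons = 2)
  subs <- unique(vt$subject_id)
  meta <- data.frame(subject_id = subs,
                     age = runif(length(subs), 55, 90),
                     sex = sample(c("F", "M"), length(subs), TRUE))
  feats <- merge(unique(tg[c("subject_id", "visit_date")]), meta,
                 by = "subject_id")
  # inject a prediction that perfectly separates z
  key <- paste(tg$subject_id, tg$visit_date)
  z_of <- setNames(tg$z[tg$horizon == 2],
                   paste(tg$subject_id, tg$visit_date)[tg$horizon == 2])
  feats$yhat <- ifelse(is.na(z_of[paste(feats$subject_id, feats$visit_date)]),
                       0.5, z_of[paste(feats$subject_id, feats$visit_date)])
  out <- run_model_suite(tg, feats, horizons = 2, k = 3, inner_k = 3, seed = 6)

  m <- out$metrics
  expect_equal(mean(m$auc[m$model == "pred"], na.rm = TRUE), 1)

  # leakage audit: no test subject ever appears in its fold's training data
  pr <- out$predictions
  for (f in unique(pr$fold)) {
    test_subs <- unique(pr$subject_id[pr$fold == f])
    other <- unique(pr$subject_id[pr$fold != f])
    expect_length(intersect(test_subs, other), 0)
  }
  # one test timepoint per subject per (horizon, model)
  counts <- table(pr$subject_id[pr$model == "pred"])
  expect_true(all(counts == 1))
})

test_that("morphological records serialize losslessly with the slope rule", {
  one <- morphological_record("s1", data.frame(visit_date = 0, yhat = 0.4))
  expect_true(is.na(one$slope_per_year))

  two <- morphological_record(
    "s2", data.frame(visit_date = c(0, 365.25), yhat = c(0.2, 0.4)))
  expect_equal(two$slope_per_year, 0.2, tolerance = 1e-12)

  rec <- morphological_record(
    "s3",
    data.frame(visit_date = c(0, 200, 420), yhat = c(0.2, 0.35, 0.6),
               map_path = sprintf("maps/s3_%d.nii.gz", 1:3)),
    progression = data.frame(horizon = 1:3, p = c(0.1, 0.4, 0.8)))
  back <- record_from_json(record_to_json(rec))
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$visits$yhat, rec$visits$yhat)
  expect_equal(back$slope_per_year, rec$slope_per_year)
  expect_equal(back$progression$p, rec$progression$p)
})
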