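test_that("percentile binarization matches a brute-force sort", {
  set.seed(60)
  m <- array(runif(100), c(100, 1, 1))
  bin <- binarize_percentile(m, 90)
  thr <- quantile(as.vector(m), 0.9, names = FALSE)
  expect_identical(as.vector(bin), as.vector(m) > thr)
  expect_equal(sum(bin), sum(sort(as.vector(m)) > thr))

  expect_true(all(!binarize_percentile(array(3, c(4, 4, 4)), 50)))
  distinct <- array(1:27, c(3, 3, 3))
  expect_equal(sum(binarize_percentile(distinct, 0)), 26)
  expect_error(binarize_percentile(m, 100))
})

test_that("dice follows the printed form with a conventional variant", {
  a <- array(FALSE, c(4, 4, 1)); a[1:3] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[2:6] <- TRUE
  # |A| = 3, |B| = 5, overlap 2
  expect_equal(dice(a, b), 2 / 8)
  expect_equal(dice(a, b, conventional = TRUE), 0.5)
  expect_equal(dice(a, a), 0.5)
  expect_equal(dice(a, a, conventional = TRUE), 1)
  disj <- array(FALSE, c(4, 4, 1)); disj[10:12] <- TRUE
  expect_equal(dice(a, disj), 0)
  empty <- array(FALSE, c(4, 4, 1))
  expect_message(v <- dice(empty, empty), "empty")
  expect_equal(v, 0)
})

test_that("dice curves separate identical, random and aligned maps", {
  set.seed(61)
  d <- c(8, 8, 8)
  g <- array(runif(prod(d)), d)

  same <- dice_curve(g, g, percentiles = c(0, 25, 50, 75, 99))
  expect_true(all(same$sdc == 0.5))
  expect_true(all(same$sdc >= 0 & same$sdc <= 1))

  r1 <- array(runif(prod(d)), d)
  rand <- dice_curve(r1, g, percentiles = c(0, 50, 90, 99))
  expect_lt(rand$sdc[4], rand$sdc[1])   # overlap decays as maps sparsen

  # a map supported exactly on the reference's hot set dominates random maps
  aligned <- g * (g > quantile(g, 0.5))
  da <- dice_curve(aligned, g, percentiles = 50:99)
  dr <- dice_curve(r1, g, percentiles = 50:99)
  expect_true(all(da$sdc >= dr$sdc))
})

test_that("ncc is a Pearson similarity with affine invariance", {
  set.seed(62)
  a <- array(rnorm(60), c(5, 4, 3))
  b <- array(rnorm(60), c(5, 4, 3))
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  expect_equal(ncc(a, 3 * b + 7), ncc(a, b), tolerance = 1e-12)

  # hand-computed 2x2x1 grids
  x <- array(c(1, 2, 3, 4), c(2, 2, 1))
  y <- array(c(1, 1, 2, 4), c(2, 2, 1))
  dx <- c(1, 2, 3, 4) - 2.5; dy <- c(1, 1, 2, 4) - 2
  expect_equal(ncc(x, y), sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)),
               tolerance = 1e-12)
  expect_error(ncc(array(1, c(2, 2, 1)), y), "constant")
})

test_that("region aggregation agrees with a per-voxel loop oracle", {
  atlas <- synthetic_atlas(grid = 10, n_regions = 4, seed = 63)
  set.seed(64)
  m <- array(runif(1000), c(10, 10, 10))

  for (stat in c("mean", "sum", "max")) {
    got <- region_aggregate(m, atlas, stat)
    for (rid in got$region) {
      vals <- c()
      for (i in 1:10) for (j in 1:10) for (k in 1:10)
        if (atlas$labels[i, j, k] == rid) vals <- c(vals, m[i, j, k])
      expected <- switch(stat, mean = mean(vals), sum = sum(vals),
                         max = max(vals))
      expect_equal(got$value[got$region == rid], expected, tolerance = 1e-12)
    }
  }

  u <- array(2.5, c(10, 10, 10))
  agg <- region_aggregate(u, atlas, "mean")
  expect_true(all(agg$value == 2.5))
  sums <- region_aggregate(u, atlas, "sum")
  expect_equal(sums$value, 2.5 * as.vector(table(atlas$labels[atlas$labels > 0])))

  hot <- array(0, c(10, 10, 10))
  vox <- which(atlas$labels == 2, arr.ind = TRUE)[1, , drop = FALSE]
  hot[vox] <- 9
  hs <- region_aggregate(hot, atlas, "sum")
  expect_equal(hs$value[hs$region == 2], 9)
  expect_true(all(hs$value[hs$region != 2] == 0))
})

test_that("average true-positive maps use the label-and-prediction filter", {
  maps <- list(array(0, c(2, 2, 2)), array(2, c(2, 2, 2)),
               array(9, c(2, 2, 2)))
  avg <- average_true_positive_map(maps, c(0.9, 0.8, 0.3), c(1, 1, 1))
  expect_true(all(avg == 1))                        # third excluded: yhat 0.3
  one <- average_true_positive_map(maps, c(0.9, 0.2, 0.2), c(1, 1, 1))
  expect_identical(one, maps[[1]])
  expect_error(average_true_positive_map(maps, c(0.4, 0.4, 0.4), c(1, 1, 1)),
               "no true positives")
})

test_that("aopc matches its closed forms", {
  expect_equal(aopc(c(0.7, 0.7, 0.7)), 0)
  expect_equal(aopc(c(1.0, 0.5)), 0.5)
  tr <- seq(0.9, by = -0.01, length.out = 21)   # linear decline over 20 steps
  expect_equal(aopc(tr), mean(0.9 - tr[-1]), tolerance = 1e-12)
  expect_equal(aopc(tr), 0.01 * mean(1:20), tolerance = 1e-12)
  expect_error(aopc(0.5), "baseline")
})

test_that("occlusion traces follow the working relevance map", {
  m <- build_model(grid = 16, blocks = 3, base_channels = 2, seed = 70)
  vol <- array(runif(16^3, 0.2, 1), c(16, 16, 16))

  t0 <- occlusion_trace(m, vol, array(1, dim(vol)) * 0, iterations = 0)
  expect_length(t0$trace, 1)
  expect_equal(t0$trace[1], predict_volumes(m, vol))

  hot <- array(0, dim(vol)); hot[9, 4, 12] <- 1
  tr <- occlusion_trace(m, vol, hot, iterations = 1, cube = 3, seed = 2)
  expect_identical(as.integer(tr$centers[1, ]), c(9L, 4L, 12L))
  expect_length(tr$trace, 2)
  expect_false(tr$fallback[1])
  expect_equal(tr$aopc, tr$trace[1] - tr$trace[2])

  # exhausted map falls back to random brain voxels, reported
  expect_message(
    trf <- occlusion_trace(m, vol, array(0, dim(vol)), iterations = 2,
                           cube = 3, seed = 3),
    "fell back")
  expect_true(all(trf$fallback))

  # deterministic under seed
  tr2 <- occlusion_trace(m, vol, hot, iterations = 1, cube = 3, seed = 2)
  expect_identical(tr$trace, tr2$trace)
})

test_that("null pipelines share the engine and degenerate correctly", {
  m <- strip_sigmoid(fuse_batchnorm(
    build_model(grid = 16, blocks = 3, base_channels = 2, seed = 71)))
  vols <- lapply(1:4, function(i) array(runif(16^3), c(16, 16, 16)))

  # sigma 0 degenerates to the constant mean image -> identical maps
  deg <- null_pipeline_maps("random_images", m, vols, sigma_scale = 0, seed = 1)
  expect_equal(deg[[1]]$values, deg[[2]]$values)
  mean_img <- Reduce(`+`, vols) / 4
  expect_equal(deg[[1]]$values, explain(m, mean_img)$values, tolerance = 1e-12)

  # random-weights maps vary with the weight seed but conserve relevance
  rw1 <- null_pipeline_maps("random_weights", m, vols[1], seed = 5,
                            blocks = 3, base_channels = 2)[[1]]
  rw2 <- null_pipeline_maps("random_weights", m, vols[1], seed = 6,
                            blocks = 3, base_channels = 2)[[1]]
  expect_gt(max(abs(rw1$values - rw2$values)), 0)

  expect_error(null_pipeline_maps("alt_task", m, vols), "alt_model")
})
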