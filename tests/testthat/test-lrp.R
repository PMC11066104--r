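test_that("dense rules reproduce hand-computed worked examples", {
  # one path: a=2, w=3, downstream 5 -> upstream 5
  expect_equal(lrp_generic(2, 3, 5), 5)
  # proportional split 1/4, 3/4
  expect_equal(lrp_generic(c(1, 1), matrix(c(1, 3), 2, 1), 4), c(1, 3))
  # epsilon: denominator 4 + 4 = 8, shares 1/8 and 3/8 of relevance 8
  expect_equal(lrp_epsilon(c(1, 1), matrix(c(1, 3), 2, 1), 8, epsilon = 4),
               c(1, 3))
  # epsilon limits
  a <- runif(4); w <- matrix(rnorm(12), 4, 3); r <- rnorm(3)
  expect_equal(lrp_epsilon(a, w, r, epsilon = 0), lrp_generic(a, w, r))
  expect_lt(max(abs(lrp_epsilon(a, w, r, epsilon = 1e12))), 1e-9)
  # alpha-beta: positive-only discards the negative path
  expect_equal(lrp_alphabeta(c(1, 1), matrix(c(2, -2), 2, 1), 1,
                             alpha = 1, beta = 0), c(1, 0))
  # all-positive layer: alpha=1/beta=0 equals generic
  ap <- runif(4); wp <- matrix(runif(12), 4, 3); rp <- runif(3)
  expect_equal(lrp_alphabeta(ap, wp, rp, alpha = 1, beta = 0),
               lrp_generic(ap, wp, rp))
  expect_error(lrp_alphabeta(ap, wp, rp, alpha = 2, beta = 0.5), "alpha")
  # flat: uniform split
  expect_equal(lrp_flat(3, 6), c(2, 2, 2))
})

test_that("dense rules match the brute-force oracle on random layers", {
  set.seed(31)
  for (trial in 1:20) {
    M <- sample(3:8, 1); N <- sample(2:6, 1)
    a <- rnorm(M); w <- matrix(rnorm(M * N), M, N)
    r <- rnorm(N); b <- rnorm(N) * sample(0:1, 1)
    expect_lt(max(abs(lrp_generic(a, w, r, b) -
                      oracle_dense(a, w, r, b, "generic"))), 1e-10)
    expect_lt(max(abs(lrp_epsilon(a, w, r, b, epsilon = 0.3) -
                      oracle_dense(a, w, r, b, "epsilon", epsilon = 0.3))),
              1e-10)
    expect_lt(max(abs(lrp_alphabeta(a, w, r, b, alpha = 2, beta = 1) -
                      oracle_dense(a, w, r, b, "alphabeta", alpha = 2,
                                   beta = 1))), 1e-10)
    expect_lt(max(abs(lrp_flat(M, r) - oracle_dense(a, w, r, 0, "flat"))),
              1e-12)
  }
  # column sums of the propagation conserve total relevance (bias-free)
  a <- runif(4) + 0.1; w <- matrix(rnorm(12), 4, 3); r <- rnorm(3)
  expect_lt(abs(sum(lrp_generic(a, w, r)) - sum(r)), 1e-10)
})

test_that("conv-space rules match the explicit-matrix oracle", {
  set.seed(32)
  dims <- c(4, 3, 3)
  w3 <- array(rnorm(27), c(3, 3, 3))
  mat <- conv_as_matrix(w3, dims)
  for (trial in 1:5) {
    a3 <- array(rnorm(prod(dims)), dims)
    r3 <- array(rnorm(prod(dims)), dims)
    for (rule in c("generic", "alphabeta", "flat")) {
      eng <- engine_conv_rule(a3, w3, r3, rule, alpha = 2, beta = 1)
      ora <- array(oracle_dense(as.vector(a3), mat, as.vector(r3), 0,
                                if (rule == "generic") "generic" else rule,
                                alpha = 2, beta = 1), dims)
      if (rule == "flat") {
        # flat counts only actual connections, not the dense M
        ones <- conv_as_matrix(array(1, c(3, 3, 3)), dims)
        cnt <- colSums(ones)
        ora <- array(as.vector(ones %*% (as.vector(r3) / cnt)), dims)
      }
      expect_lt(max(abs(eng - ora)), 1e-10)
    }
  }
})

test_that("flat rule connectivity respects borders", {
  # 1-D analogue: 5x1x1 grid, kernel 3 -> interior |o| = 3, border |o| = 2
  dims <- c(5, 1, 1)
  a3 <- array(1, dims)
  r3 <- array(1, dims)
  w3 <- array(1, c(3, 3, 3))
  out <- engine_conv_rule(a3, w3, r3, "flat")
  # border downstream neurons split over fewer upstream units (|o| = 2 vs 3),
  # so each of their connections carries a larger share
  expect_equal(sum(out), sum(r3), tolerance = 1e-12)
  expect_equal(out[1, 1, 1], 1 / 2 + 1 / 3)    # shares from downstream 1, 2
  expect_equal(out[2, 1, 1], 1 / 2 + 1 / 3 + 1 / 3)
  expect_equal(out[3, 1, 1], 1 / 3 + 1 / 3 + 1 / 3)
  expect_gt(out[2, 1, 1], out[3, 1, 1])
})

test_that("rules conserve relevance layer-wise on bias-free fixtures", {
  set.seed(33)
  dims <- c(4, 4, 4)
  for (trial in 1:10) {
    a3 <- array(rnorm(prod(dims)), dims)
    w3 <- array(rnorm(27), c(3, 3, 3))
    r3 <- array(rexp(prod(dims)), dims)
    for (rule in c("generic", "alphabeta", "flat")) {
      out <- engine_conv_rule(a3, w3, r3, rule, alpha = 1, beta = 0)
      expect_lt(abs(sum(out) - sum(r3)) / sum(r3), 1e-8)
    }
    # scale covariance: relevance is linear in the incoming seed
    out1 <- engine_conv_rule(a3, w3, r3, "alphabeta", alpha = 1, beta = 0)
    out2 <- engine_conv_rule(a3, w3, 2.5 * r3, "alphabeta", alpha = 1, beta = 0)
    expect_equal(out2, 2.5 * out1, tolerance = 1e-12)
  }
})

test_that("explain produces conservative maps on a fused logit-mode model", {
  m <- build_model(grid = 16, blocks = 3, base_channels = 4, seed = 44)
  m <- relmap3d:::zero_biases(m)
  mf <- strip_sigmoid(fuse_batchnorm(m))
  vol <- array(runif(16^3), c(16, 16, 16))

  expect_error(explain(fuse_batchnorm(m), vol), "logit mode")
  expect_error(explain(strip_sigmoid(m), vol), "batchnorm")
  expect_error(explain(mf, array(0, c(8, 8, 8))), "grid")

  for (preset in c("generic", "composite")) {
    ra <- rule_assignment(mf, preset, epsilon = 0)
    ex <- explain(mf, vol, ra)
    expect_identical(dim(ex$values), dim(vol))
    expect_true(all(is.finite(ex$values)))
    expect_lt(abs(sum(ex$values) - ex$yhat_logit) /
                max(abs(ex$yhat_logit), 1e-12), 1e-4)
    expect_equal(ex$yhat, plogis(ex$yhat_logit))
  }

  # all-zero input through a bias-free network: zero logit, zero relevance
  ex0 <- explain(mf, array(0, c(16, 16, 16)))
  expect_equal(ex0$yhat_logit, 0)
  expect_true(all(ex0$values == 0))
})

test_that("ensemble explanation averages predictions and relevance", {
  m1 <- strip_sigmoid(fuse_batchnorm(
    build_model(grid = 16, blocks = 3, base_channels = 2, seed = 1)))
  m2 <- strip_sigmoid(fuse_batchnorm(
    build_model(grid = 16, blocks = 3, base_channels = 2, seed = 2)))
  vol <- array(runif(16^3), c(16, 16, 16))

  single <- explain(m1, vol)
  same <- ensemble_explain(list(m1, m1, m1), vol)
  expect_equal(same$values, single$values)
  expect_equal(same$yhat, single$yhat)

  both <- ensemble_explain(list(m1, m2), vol)
  e1 <- explain(m1, vol); e2 <- explain(m2, vol)
  expect_equal(both$values, (e1$values + e2$values) / 2)
  expect_equal(sum(both$values), (sum(e1$values) + sum(e2$values)) / 2)

  m3 <- strip_sigmoid(fuse_batchnorm(
    build_model(grid = 8, blocks = 2, base_channels = 2, seed = 3)))
  expect_error(ensemble_explain(list(m1, m3), vol), "grid")
})

test_that("relevance maps serialize with their JSON sidecar", {
  m <- strip_sigmoid(fuse_batchnorm(
    build_model(grid = 16, blocks = 3, base_channels = 2, seed = 9)))
  ex <- explain(m, array(runif(16^3), c(16, 16, 16)))
  path <- tempfile(fileext = ".nii.gz")
  write_relevance_map(ex, path)
  back <- read_nifti(path)
  expect_lt(max(abs(back - ex$values)), 1e-6)
  side <- jsonlite::fromJSON(sub("\\.nii\\.gz$", ".json", path))
  expect_equal(side$yhat, ex$yhat, tolerance = 1e-12)
  expect_identical(side$preset, "composite")
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
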