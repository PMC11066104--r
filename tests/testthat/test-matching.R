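test_that("history enumeration varies start and terminal visits", {
  expect_length(enumerate_histories(c(0, 100)), 1)
  h4 <- enumerate_histories(c(0, 100, 250, 400))
  expect_length(h4, 6)                        # pairs i < j of start/terminal
  expect_setequal(lengths(h4), 2:4)
  for (h in h4) {
    expect_equal(h[length(h)], 0)
    expect_true(all(diff(h) < 0))
    expect_true(all(h >= 0))
  }
  expect_error(enumerate_histories(5), "at least 2")
  expect_error(enumerate_histories(c(0, 100, 100)), "strictly increasing")
})

test_that("progressive histories end at the first dementia visit", {
  h <- progressive_history(c(0, 200, 450, 700), c("MCI", "MCI", "DEM", "DEM"))
  expect_equal(h, c(450, 250, 0))
  expect_null(progressive_history(c(0, 100), c("MCI", "MCI")))
  expect_null(progressive_history(c(0, 100), c("DEM", "DEM")))
})

test_that("history cost is the worked absolute-difference sum", {
  expect_equal(history_cost(c(400, 200, 0), c(380, 230, 0)), 50)
  expect_equal(history_cost(c(400, 200, 0), c(400, 200, 0)), 0)
  a <- c(300, 100, 0); b <- c(280, 160, 0)
  expect_equal(history_cost(a, b), history_cost(b, a))
  expect_error(history_cost(c(1, 0), c(2, 1, 0)), "equal length")
})

test_that("best pair cost minimizes over equal-length candidates", {
  cands <- enumerate_histories(c(0, 90, 210, 390))
  target <- c(400, 180, 0)
  got <- best_pair_cost(target, cands)
  brute <- Inf
  for (h in cands) if (length(h) == 3) brute <- min(brute, sum(abs(h - target)))
  expect_equal(as.numeric(got), brute)
  expect_equal(best_pair_cost(c(1000, 900, 800, 700, 0), cands), Inf)
  single <- best_pair_cost(c(100, 0), list(c(90, 0)))
  expect_equal(as.numeric(single), 10)
})

test_that("assignment is globally optimal against permutation brute force", {
  res1 <- assign_matches(matrix(3.5, 1, 1))
  expect_equal(res1$total_cost, 3.5)
  expect_equal(nrow(res1$pairs), 1)

  brute_min <- function(m) {
    n <- nrow(m)
    best <- Inf
    for (p in asplit(gtools_perms(n), 1)) {
      tot <- sum(m[cbind(seq_len(n), p)])
      best <- min(best, tot)
    }
    best
  }
  gtools_perms <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- gtools_perms(n - 1)
    out <- NULL
    for (i in seq_len(n)) {
      block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
      out <- rbind(out, block)
    }
    out
  }

  set.seed(80)
  for (trial in 1:30) {
    m <- matrix(sample(0:500, 25), 5, 5)
    expect_equal(assign_matches(m)$total_cost, brute_min(m))
  }

  # permuting rows permutes the assignment identically
  m <- matrix(sample(0:99, 16), 4, 4)
  res <- assign_matches(m)
  perm <- c(3, 1, 4, 2)
  resp <- assign_matches(m[perm, ])
  expect_equal(resp$total_cost, res$total_cost)
  lookup <- setNames(res$pairs$nonprogressive, res$pairs$progressive)
  lookupp <- setNames(resp$pairs$nonprogressive, resp$pairs$progressive)
  for (r in seq_len(4))
    expect_identical(lookupp[[as.character(r)]],
                     lookup[[as.character(perm[r])]])

  # Inf entries are never selected; unmatchable rows are excluded
  mi <- rbind(c(1, Inf), c(Inf, Inf))
  expect_message(resi <- assign_matches(mi), "no finite-cost match")
  expect_equal(nrow(resi$pairs), 1)
  expect_identical(resi$unmatched, "2")
  expect_equal(resi$total_cost, 1)

  # rectangular: every row matched when finite columns abound
  mr <- matrix(runif(12), 3, 4)
  expect_equal(nrow(assign_matches(mr)$pairs), 3)
})

test_that("planted twin schedules are recovered exactly at zero noise", {
  set.seed(81)
  n <- 20
  rows <- list()
  for (i in seq_len(n)) {
    nv <- sample(3:5, 1)
    days <- c(0, cumsum(sample(150:400, nv - 1, TRUE)))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("prog_%02d", i), visit_date = days,
      diagnosis = c(rep("MCI", nv - 1), "DEM"))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("twin_%02d", i), visit_date = days,
      diagnosis = rep("MCI", nv))
  }
  visits <- do.call(rbind, rows)
  res <- match_visit_histories(visits)
  expect_equal(res$total_cost, 0)
  hits <- sum(sub("prog", "twin", res$pairs$progressive) ==
                res$pairs$nonprogressive)
  expect_gte(hits / n, 0.95)
})

test_that("trajectory grammar classification covers the cases", {
  expect_identical(classify_trajectory(c("MCI", "MCI")), "stable")
  expect_identical(classify_trajectory(c("MCI", "CN", "CN")), "improving")
  expect_identical(classify_trajectory(c("MCI", "DEM", "DEM")), "progressive")
  expect_identical(classify_trajectory(c("MCI", "DEM", "MCI")), "ambiguous")
  expect_identical(classify_trajectory(c("MCI", "CN", "DEM")), "ambiguous")
  expect_identical(classify_trajectory(c("CN", "CN")), "ambiguous")
})
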