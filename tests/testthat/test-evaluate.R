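test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  # per-class recalls (1.0, 0.5, 0.0) average to 0.5
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 1, 2, 3, 1, 2)
  expect_equal(balanced_accuracy(truth, pred), 0.5)
  # equals plain accuracy on a balanced test set
  set.seed(1)
  t_bal <- rep(1:3, each = 10)
  p_bal <- sample(1:3, 30, replace = TRUE)
  expect_equal(balanced_accuracy(t_bal, p_bal), mean(p_bal == t_bal))
  expect_error(balanced_accuracy(integer(0), integer(0)), "empty")
  # brute-force oracle over random confusion settings
  for (i in 1:100) {
    set.seed(i)
    k <- sample(2:5, 1)
    n <- sample(3:20, 1)
    truth <- sample(seq_len(k), n, replace = TRUE)
    pred <- sample(seq_len(k), n, replace = TRUE)
    oracle <- mean(sapply(unique(truth), function(cl) {
      idx <- which(truth == cl)
      sum(pred[idx] == cl) / length(idx)
    }))
    expect_equal(balanced_accuracy(truth, pred), oracle)
  }
})

test_that("expected calibration error follows the binned definition", {
  # perfectly confident and correct
  P <- diag(3)[c(1, 2, 3), ]
  expect_equal(expected_calibration_error(P, c(1, 2, 3)), 0)
  # single-bin hand computation: conf 0.8, 6 of 10 correct -> 0.2
  P <- matrix(c(0.8, 0.1, 0.1), 10, 3, byrow = TRUE)
  truth <- c(rep(1, 6), rep(2, 4))
  expect_equal(expected_calibration_error(P, truth), 0.2)
  # order invariance
  set.seed(2)
  P <- t(apply(matrix(runif(60), 20), 1, function(r) r / sum(r)))
  truth <- sample(1:3, 20, replace = TRUE)
  perm <- sample(20)
  expect_equal(expected_calibration_error(P, truth),
               expected_calibration_error(P[perm, ], truth[perm]))
  expect_error(expected_calibration_error(P[0, ], integer(0)), "empty")
  # brute-force oracle over random prediction sets
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:50, 1)
    P <- t(apply(matrix(runif(3 * n), n), 1, function(r) r / sum(r)))
    truth <- sample(1:3, n, replace = TRUE)
    conf <- apply(P, 1, max)
    correct <- apply(P, 1, which.max) == truth
    oracle <- 0
    for (b in 1:10) {
      in_b <- conf > (b - 1) / 10 & conf <= b / 10
      if (b == 1) in_b <- in_b | conf == 0
      if (any(in_b))
        oracle <- oracle +
          sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
    }
    expect_equal(expected_calibration_error(P, truth), oracle)
  }
})

test_that("the stability delta is the spread of per-level medians", {
  expect_equal(delta_stability(c(0.8, 0.6, 0.5)), 0.3)
  expect_equal(delta_stability(rep(0.42, 7)), 0)
  set.seed(3)
  v <- runif(7)
  expect_equal(delta_stability(v), delta_stability(sample(v)))
  expect_error(delta_stability(numeric(0)), "empty")
})

test_that("the above-chance threshold is the binomial quantile", {
  expect_equal(chance_threshold(90, 1 / 3, 0.05), 37 / 90)
  expect_equal(chance_threshold(1, 1 / 3, 0.05), 1)
  expect_lt(chance_threshold(1e5, 1 / 3, 0.05) - 1 / 3, 0.01)
  expect_error(chance_threshold(0, 1 / 3, 0.05), "invalid")
  expect_error(chance_threshold(90, 0, 0.05), "invalid")
  # exact against direct CDF enumeration for n <= 200
  for (i in 1:100) {
    set.seed(i)
    n <- sample(1:200, 1)
    p <- runif(1, 0.05, 0.95)
    alpha <- runif(1, 0.01, 0.2)
    cdf <- cumsum(dbinom(0:n, n, p))
    q <- (0:n)[which(cdf >= 1 - alpha - 1e-12)[1]]
    expect_equal(chance_threshold(n, p, alpha), q / n)
  }
})

test_that("Fleiss' kappa matches an independent pairwise-agreement oracle", {
  # perfect agreement
  all_agree <- matrix(c(4, 0, 0), 10, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(all_agree), 1)
  # hand-evaluated 4-item example, 4 raters
  counts <- rbind(c(3, 1, 0), c(2, 2, 0), c(4, 0, 0), c(2, 1, 1))
  r <- 4
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(counts) / (4 * r)
  Pe <- sum(p_j^2)
  expect_equal(fleiss_kappa(counts), (Pbar - Pe) / (1 - Pe))
  expect_error(fleiss_kappa(rbind(c(2, 1, 0), c(1, 1, 1), c(3, 1, 0))),
               "row sums")
  # oracle from raw ratings: agreement counted over explicit rater pairs
  for (i in 1:100) {
    set.seed(i)
    n_items <- sample(4:15, 1)
    n_raters <- sample(2:6, 1)
    k <- sample(2:4, 1)
    ratings <- matrix(sample(seq_len(k), n_items * n_raters, replace = TRUE),
                      n_items, n_raters)
    counts <- t(apply(ratings, 1, tabulate, nbins = k))
    pairs <- utils::combn(n_raters, 2)
    agree <- mean(apply(ratings, 1, function(row)
      mean(row[pairs[1, ]] == row[pairs[2, ]])))
    p_j <- tabulate(ratings, k) / length(ratings)
    Pe <- sum(p_j^2)
    if (abs(1 - Pe) < 1e-12) next
    expect_equal(fleiss_kappa(counts), (agree - Pe) / (1 - Pe))
  }
  # random ratings over many items give kappa near zero
  set.seed(99)
  ratings <- matrix(sample(1:3, 3000 * 4, replace = TRUE), 3000, 4)
  counts <- t(apply(ratings, 1, tabulate, nbins = 3))
  expect_lt(abs(fleiss_kappa(counts)), 0.05)
})

test_that("the rater protocol enumerates the full trial grid", {
  proto <- build_rater_protocol(4, 30, 0:6)
  expect_identical(nrow(proto$trials), 840L)
  expect_identical(nrow(build_rater_protocol(1, 30, 0:6)$trials), 210L)
  expect_identical(nrow(build_rater_protocol(1, 1, 3)$trials), 1L)
  expect_identical(names(proto$response_template),
                   c("rater_id", "item_id", "level", "response"))
  # every rater sees every item exactly once
  expect_true(all(table(proto$trials$rater_id) == 210))
  expect_true(all(table(proto$trials$item_id) == 4))
})

test_that("report aggregation medians, deltas, flags, and round-trips", {
  runs <- c(0.3, 0.5, 0.4, 0.6, 0.5)
  cells <- expand.grid(run = 1:5, level = 0:2)
  cells$strategy <- "vanilla"
  cells$family <- "gaussian"
  cells$balanced_accuracy <- runs[cells$run] + 0.1 * cells$level
  cells$ece <- 0.1
  rep <- aggregate_report(cells, n_test = 90)
  m0 <- rep$medians[rep$medians$level == 0, ]
  expect_equal(m0$median_balanced_accuracy, 0.5)   # 3rd order statistic
  expect_equal(rep$deltas$delta, 0.2)
  expect_equal(rep$threshold, 37 / 90)
  expect_true(all(rep$medians$above_chance ==
                    (rep$medians$median_balanced_accuracy > 37 / 90)))
  # median 0.42 vs threshold 0.411 flags above-chance
  one <- data.frame(strategy = "s", run = 1, family = "gaussian", level = 0,
                    balanced_accuracy = 0.42, ece = 0.2)
  rep1 <- aggregate_report(one, n_test = 90)
  expect_true(rep1$medians$above_chance)
  expect_equal(rep1$medians$median_balanced_accuracy, 0.42)  # single run
  # disk round-trip preserves the aggregates
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$medians, rep$medians)
  expect_equal(back$deltas, rep$deltas)
  expect_equal(back$threshold, rep$threshold)
})
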