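# Independent brute-force recomputations (plain loops, no shared code with
# the implementation) used as oracles throughout this file.
bf_mae <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - t[i])
  s / length(p)
}
bf_rmse <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
  sqrt(s / length(p))
}
bf_r2 <- function(p, t) {
  mp <- sum(p) / length(p); mt <- sum(t) / length(t)
  num <- sum((p - mp) * (t - mt))
  (num / sqrt(sum((p - mp)^2) * sum((t - mt)^2)))^2
}
bf_skew <- function(d) {
  m <- sum(d) / length(d)
  s2 <- sum((d - m)^2) / length(d)
  (sum((d - m)^3) / length(d)) / s2^1.5
}

test_that("regression metrics match brute force on random vectors", {
  set.seed(100)
  for (rep in 1:100) {
    n <- sample(5:1000, 1)
    p <- runif(n, 70, 100)
    t <- runif(n, 70, 100)
    r <- regression_metrics(p, t)
    expect_equal(r$mae, bf_mae(p, t), tolerance = 1e-10)
    expect_equal(r$a_rms, bf_rmse(p, t), tolerance = 1e-10)
    expect_equal(r$r2, bf_r2(p, t), tolerance = 1e-10)
  }
})

test_that("regression metric worked examples hold", {
  r <- regression_metrics(c(1, 2, 3), c(2, 2, 5))
  expect_equal(r$mae, 1.0)
  expect_equal(r$a_rms, sqrt(5 / 3))
  exact <- regression_metrics(70:80, 70:80)
  expect_equal(exact$mae, 0)
  expect_equal(exact$a_rms, 0)
  expect_equal(exact$r2, 1)
  offset <- regression_metrics(70:80 + 2, 70:80)
  expect_equal(offset$mae, 2)
  expect_equal(offset$r2, 1)
  flat <- regression_metrics(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(flat$r2))
  expect_match(flat$note, "undefined")
})

test_that("Bland-Altman matches brute force and its worked example", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:500, 1)
    p <- runif(n, 70, 100)
    t <- runif(n, 70, 100)
    ba <- bland_altman(p, t)
    d <- p - t
    expect_equal(ba$mean_diff, sum(d) / n, tolerance = 1e-10)
    expect_equal(ba$loa, 1.96 * sqrt(sum((d - mean(d))^2) / (n - 1)), tolerance = 1e-10)
    expect_equal(ba$skew, bf_skew(d), tolerance = 1e-10)
  }
  # worked example: differences (-1, 0, 1) have sd = 1 -> LOA exactly 1.96
  ba <- bland_altman(c(0, 1, 2) + c(-1, 0, 1), c(0, 1, 2))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa, 1.96)
  expect_equal(bland_altman(70:75, 70:75)$loa, 0)
  # symmetric differences have zero skew
  expect_lt(abs(bland_altman(c(-2, -1, 0, 1, 2), rep(0, 5))$skew), 1e-9)
  # population convention flag divides by n
  ba3 <- bland_altman(c(-1, 0, 1), c(0, 0, 0), sd_type = "population")
  expect_equal(ba3$loa, 1.96 * sqrt(2 / 3))
})

test_that("screening confusion counts enumerate correctly", {
  s <- screen(c(89, 91), c(85, 95), threshold = 90, boundary = 90)
  expect_equal(c(s$tp, s$tn, s$fp, s$fn), c(1, 1, 0, 0))
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  swapped <- screen(c(91, 89), c(85, 95), threshold = 90, boundary = 90)
  expect_equal(swapped$sensitivity, 0)
  expect_equal(swapped$specificity, 0)
  all_pos <- screen(c(80, 85), c(85, 95), threshold = 90, boundary = 100)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  none <- screen(c(95, 96), c(95, 96), threshold = 70, boundary = 90)
  expect_true(is.na(none$sensitivity))
  # ties: a value exactly at the cut counts as NOT below
  tie <- screen(90, 90, threshold = 90, boundary = 90)
  expect_equal(tie$tn, 1)
})

test_that("screening against brute-force counting on random vectors", {
  set.seed(102)
  for (rep in 1:100) {
    n <- sample(10:300, 1)
    p <- runif(n, 70, 100)
    t <- runif(n, 70, 100)
    th <- runif(1, 75, 95); b <- runif(1, 75, 95)
    s <- screen(p, t, th, b)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (t[i] < th) { if (p[i] < b) tp <- tp + 1 else fn <- fn + 1 }
      else           { if (p[i] < b) fp <- fp + 1 else tn <- tn + 1 }
    }
    expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(tp, fp, tn, fn))
    if (tp + fn > 0) expect_equal(s$sensitivity, tp / (tp + fn), tolerance = 1e-10)
    if (tn + fp > 0) expect_equal(s$specificity, tn / (tn + fp), tolerance = 1e-10)
  }
})

test_that("ROC sweep: separable predictions give AUC 1, noise gives ~0.5", {
  truth <- c(rep(80, 50), rep(95, 50))
  perfect <- list(list(pred = truth, truth = truth))
  r <- roc_sweep(perfect, threshold = 90, boundaries = seq(70, 100, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$best_point$sensitivity, 1)
  expect_equal(r$best_point$specificity, 1)
  set.seed(103)
  noise <- list(list(pred = runif(4000, 70, 100), truth = runif(4000, 70, 100)))
  r2 <- roc_sweep(noise, threshold = 85, boundaries = seq(70, 100, 0.5))
  expect_lt(abs(r2$auc - 0.5), 0.05)
})

test_that("trapezoid AUC matches the pairwise-comparison estimator", {
  set.seed(104)
  for (rep in 1:5) {
    n <- 400
    truth <- runif(n, 70, 100)
    pred <- truth + rnorm(n, 0, 6)
    th <- 88
    r <- roc_sweep(list(list(pred = pred, truth = truth)), threshold = th,
                   boundaries = seq(60, 110, 0.25))
    pos <- pred[truth < th]
    neg <- pred[truth >= th]
    # probability a positive scores below a negative (ties half)
    cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 0.02)
  }
})

test_that("ROC curve is monotone with unit endpoints after sorting", {
  set.seed(105)
  pred <- runif(300, 70, 100)
  truth <- pred + rnorm(300, 0, 5)
  r <- roc_sweep(list(list(pred = pred, truth = truth)), threshold = 90)
  o <- order(r$roc$fpr, r$roc$tpr)
  expect_true(all(diff(r$roc$tpr[o]) >= -1e-12))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
})

test_that("signed-rank: n = 6 all-positive differences give exact p = 1/64", {
  x <- c(5.1, 4.2, 6.3, 5.5, 4.8, 5.9)
  y <- x - c(1, 2, 1.5, 0.7, 1.1, 2.2)
  res <- paired_signed_rank(x, y, alternative = "greater")
  # enumeration oracle: all 2^6 sign patterns of the ranks
  d <- x - y
  ranks <- rank(abs(d))
  W <- sum(ranks[d > 0])
  all_W <- vapply(0:(2^6 - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:6]
    sum(ranks[signs == 1])
  }, numeric(1))
  p_exact <- mean(all_W >= W)
  expect_equal(res$p_value, p_exact)
  expect_equal(p_exact, 1 / 64)
})

test_that("signed-rank is invariant to a common shift and flags degeneracy", {
  x <- c(1.25, 3.5, 2.25, 5, 4.5, 3)
  d <- c(0.5, -0.75, 0.875, 1, -1.25, 1.5)  # distinct magnitudes, no ties
  y <- x - d
  a <- paired_signed_rank(x, y)
  b <- paired_signed_rank(x + 128, y + 128)  # exact in binary floating point
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("identical pairs carry no evidence: p = 1, flagged degenerate", {
  x <- c(10, 11, 12, 13, 14, 15)
  res <- paired_signed_rank(x, x)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})
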