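test_that("IQR fences exclude the right points", {
  fl <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(fl$kept, c(1, 2, 3, 4))
  expect_equal(fl$excluded, 100)

  same <- iqr_filter(rep(5, 10))
  expect_equal(same$kept, rep(5, 10))
  expect_length(same$excluded, 0)

  expect_warning(short <- iqr_filter(c(1, 2, 3)), "fewer than 4")
  expect_equal(short$kept, c(1, 2, 3))
})

test_that("IQR filtering is order-preserving; empty exclusion is idempotent", {
  set.seed(5)
  n_empty <- 0
  for (i in 1:50) {
    v <- stats::rnorm(30)
    fl <- iqr_filter(v)
    # kept is a subset of the input with order preserved
    expect_identical(fl$kept, v[v %in% fl$kept])
    expect_equal(length(fl$kept) + length(fl$excluded), length(v))
    if (length(fl$excluded) == 0) {
      n_empty <- n_empty + 1
      # filtering an untouched sample again removes nothing
      expect_length(iqr_filter(fl$kept)$excluded, 0)
    }
  }
  expect_gt(n_empty, 10)   # the idempotence branch was actually exercised
})

test_that("Pearson test matches the t transform", {
  pt <- pearson_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt$r, 1)
  expect_lt(pt$p, 1e-10)

  # ratio-scaled: the value is ~7.7e-9, within a few % of the printed 7.85e-9
  expect_lt(abs(pearson_p_from_r(0.628, 69) / 7.85e-9 - 1), 0.03)

  expect_error(pearson_test(rep(1, 5), 1:5), "variance")

  # affine invariance of the p-value
  set.seed(8)
  x <- stats::rnorm(25); y <- 0.4 * x + stats::rnorm(25)
  p1 <- pearson_test(x, y)$p
  p2 <- pearson_test(3 * x - 7, -2 * y + 1)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the null rejection rate of the correlation test is calibrated", {
  set.seed(123)
  rej <- mean(replicate(2000, {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    pearson_test(x, y)$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  av <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(av$F, 3.0, tolerance = 1e-12)
  expect_equal(av$df_between, 2)
  expect_equal(av$df_within, 6)

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(2)
  a <- stats::rnorm(12); b <- stats::rnorm(15, mean = 0.5)
  av2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(av2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av2$p, tt$p.value, tolerance = 1e-10)
})

test_that("studentized-range critical value matches numerical integration", {
  q <- stats::qtukey(0.95, nmeans = 3, df = 10)
  expect_equal(q, 3.88, tolerance = 0.005)
  expect_equal(srange_cdf_numint(q, 3, 10), 0.95, tolerance = 1e-4)
})

test_that("Tukey-Kramer behaves at the edge cases", {
  same <- tukey_kramer(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_false(any(same$significant))

  # two groups reduce to the unadjusted equal-variance t test
  set.seed(4)
  for (i in 1:20) {
    a <- stats::rnorm(10); b <- stats::rnorm(10, mean = stats::runif(1, 0, 1.5))
    tk <- tukey_kramer(list(a, b), alpha = 0.05)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(tk$significant[1], tt$p.value < 0.05)
    expect_equal(tk$p_adj[1], tt$p.value, tolerance = 1e-5)
  }
})

test_that("Tukey-Kramer is conservative relative to pairwise t tests", {
  set.seed(9)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    gr <- lapply(seq_len(k), function(j)
      stats::rnorm(sample(5:12, 1), mean = stats::runif(1, 0, 1)))
    tk <- tukey_kramer(gr, alpha = 0.05)
    t_sig <- mapply(function(i, j)
      stats::t.test(gr[[i]], gr[[j]], var.equal = TRUE)$p.value < 0.05,
      tk$i, tk$j)
    expect_true(sum(tk$significant) <= sum(t_sig))
  }
})

test_that("ROC analysis matches brute-force pair counting", {
  roc <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(roc$auroc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)

  tied <- roc_analysis(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(tied$auroc, 0.875)

  set.seed(6)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    sc <- round(stats::rnorm(n), 1)           # many ties
    lb <- stats::rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    roc <- roc_analysis(sc, lb)
    expect_equal(roc$auroc, auroc_brute(sc, lb), tolerance = 1e-12)
    inv <- roc_analysis(sc, 1 - lb)
    expect_equal(inv$auroc, 1 - roc$auroc, tolerance = 1e-12)
    expect_true(roc$ci95[1] <= roc$auroc && roc$auroc <= roc$ci95[2])
  }

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- stats::rnorm(80)
  lb <- stats::rbinom(80, 1, 0.5)
  ours <- roc_analysis(sc, lb)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})
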