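test_that("Lin's CCC matches the closed formula and bands correctly", {
  x <- c(1, 2, 3)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(x, x)$band, "good")
  # location shift of 1: 2*(2/3) / ((2/3)+(2/3)+1) = 4/7
  r <- lin_ccc(x, c(2, 3, 4))
  expect_equal(r$ccc, 4 / 7)
  expect_equal(r$band, "moderate")
  expect_lt(lin_ccc(x, -x)$ccc, 0)
  expect_equal(lin_ccc(x, -x)$band, "poor")
  # both constant and equal: undefined
  expect_true(is.na(lin_ccc(rep(2, 3), rep(2, 3))$ccc))
  expect_error(lin_ccc(1:2, 1:2), "length >= 3")
})

test_that("CCC equals the definition oracle and never exceeds |Pearson r|", {
  set.seed(14)
  for (i in 1:50) {
    x <- rnorm(10); y <- 0.6 * x + rnorm(10, sd = runif(1, 0.1, 2)) +
      runif(1, -2, 2)
    r <- lin_ccc(x, y)
    expect_equal(r$ccc, ccc_oracle(x, y))
    expect_lte(abs(r$ccc), abs(cor(x, y)) + 1e-12)
  }
})

test_that("pooled-variance t test matches the textbook formula", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  tt <- two_group_t(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_hand)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), df = 4))
  # identical groups
  id <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  # widely separated groups with tiny variance
  expect_lt(two_group_t(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01))$p, 1e-6)
  # zero pooled variance is reported, not an error
  expect_true(two_group_t(rep(1, 3), rep(2, 3))$degenerate)
})

test_that("categorical test picks chi-square or Fisher appropriately", {
  # perfectly proportional table: statistic 0, p = 1
  prop <- matrix(c(10, 20, 20, 40), 2)
  ct <- categorical_test(prop)
  expect_equal(ct$method, "chisq")
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p, 1)
  # small counts fall back to Fisher, equal to hypergeometric enumeration
  for (tab in list(matrix(c(1, 5, 6, 2), 2), matrix(c(3, 1, 1, 3), 2),
                   matrix(c(0, 4, 5, 1), 2))) {
    ct <- categorical_test(tab)
    expect_equal(ct$method, "fisher")
    expect_equal(ct$p, fisher_enum_oracle(tab), tolerance = 1e-10)
  }
  # the tumor-size 2x2 of the reference cohort is significant
  expect_lt(categorical_test(matrix(c(30, 10, 6, 20), 2))$p, 0.05)
  expect_error(categorical_test(matrix(0L, 2, 2)), "all-zero")
  expect_error(categorical_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("ROC on perfectly separated groups is perfect", {
  vals <- c(0.5, 0.6, 0.9, 1.0)
  labs <- c("responder", "responder", "non-responder", "non-responder")
  r <- roc_analysis(vals, labs, direction = "lower")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 0.6)
  expect_lt(r$cutoff, 0.9)
  # degenerate single-valued predictor
  expect_equal(roc_analysis(rep(1, 4), labs)$auc, 0.5)
})

test_that("ROC AUC equals the brute-force pairwise U-statistic (fuzz)", {
  set.seed(101)
  for (i in 1:300) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(seq(0, 2, by = 0.25), n1 + n2, replace = TRUE)
    labs <- rep(c("responder", "non-responder"), c(n1, n2))
    r <- roc_analysis(vals, labs, direction = "higher")
    expect_equal(r$auc, pairwise_auc_oracle(vals[seq_len(n1)],
                                            vals[-seq_len(n1)]))
  }
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  vals <- c(rnorm(30, 1), rnorm(20, 2))
  labs <- rep(c("responder", "non-responder"), c(30, 20))
  r <- roc_analysis(vals, labs, direction = "lower")
  pr <- pROC::roc(labs, vals, levels = c("non-responder", "responder"),
                  direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci95, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("no other observed threshold beats the Youden cutoff", {
  set.seed(77)
  for (i in 1:30) {
    vals <- round(c(rnorm(12, 1), rnorm(9, 1.8)), 1)
    labs <- rep(c("responder", "non-responder"), c(12, 9))
    r <- roc_analysis(vals, labs)
    grid <- sort(unique(vals))
    cand <- c(grid[1] - 1, (grid[-1] + grid[-length(grid)]) / 2,
              grid[length(grid)] + 1)
    pos <- vals[labs == "responder"]; neg <- vals[labs != "responder"]
    j_all <- vapply(cand, function(cc) {
      if (r$orientation == "lower") mean(pos <= cc) + mean(neg > cc) - 1
      else mean(pos >= cc) + mean(neg < cc) - 1
    }, numeric(1))
    expect_gte(r$youden, max(j_all) - 1e-12)
    # cutoff stays inside the observed range
    expect_gte(r$cutoff, min(vals))
    expect_lte(r$cutoff, max(vals))
  }
})

test_that("shuffled labels give a null AUC near one half", {
  set.seed(88)
  vals <- rnorm(40)
  aucs <- replicate(200, {
    labs <- sample(rep(c("responder", "non-responder"), c(20, 20)))
    roc_analysis(vals, labs, direction = "higher")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("paired AUC comparison matches the structural-components oracle", {
  set.seed(202)
  for (i in 1:10) {
    n1 <- 5; n2 <- 5
    a <- rnorm(n1 + n2); bb <- a * 0.5 + rnorm(n1 + n2)
    labs <- rep(c("responder", "non-responder"), c(n1, n2))
    cmp <- compare_auc(a, bb, labs, direction_a = "higher",
                       direction_b = "higher")
    orc <- delong_paired_oracle(a, bb, labs == "responder")
    expect_equal(cmp$auc_a, orc$auc_a)
    expect_equal(cmp$auc_b, orc$auc_b)
    expect_equal(cmp$p, orc$p, tolerance = 1e-10)
  }
  # identical predictors cannot differ
  labs <- rep(c("responder", "non-responder"), c(6, 6))
  x <- rnorm(12)
  expect_equal(compare_auc(x, x, labs, direction_a = "higher",
                           direction_b = "higher")$p, 1)
})

test_that("paired DeLong test agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(303)
  labs <- rep(c("responder", "non-responder"), c(25, 20))
  x <- rnorm(45) + (labs == "responder") * 1.2
  y <- rnorm(45) + (labs == "responder") * 0.5
  cmp <- compare_auc(x, y, labs, direction_a = "higher",
                     direction_b = "higher")
  r1 <- pROC::roc(labs, x, levels = c("non-responder", "responder"),
                  direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labs, y, levels = c("non-responder", "responder"),
                  direction = "<", quiet = TRUE)
  pr <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(cmp$p, pr$p.value, tolerance = 1e-8)
})

test_that("a strong predictor beats a random one decisively", {
  set.seed(404)
  labs <- rep(c("responder", "non-responder"), c(60, 60))
  strong <- (labs == "responder") * 2 + rnorm(120, sd = 0.3)
  noise <- rnorm(120)
  expect_lt(compare_auc(strong, noise, labs, direction_a = "higher",
                        direction_b = "auto")$p, 0.05)
})

test_that("binormal AUC has the right closed-form values and limits", {
  expect_equal(binormal_auc(1, 1, 1, 2), 0.5)
  # reference DDC group moments: Phi(0.426 / sqrt(0.141^2 + 0.167^2))
  expect_equal(binormal_auc(0.831, 0.141, 1.257, 0.167),
               pnorm(0.426 / sqrt(0.141^2 + 0.167^2)))
  expect_equal(binormal_auc(0.831, 0.141, 1.257, 0.167), 0.974,
               tolerance = 5e-4)
  expect_gt(binormal_auc(0, 1, 100, 1), 1 - 1e-12)
})
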