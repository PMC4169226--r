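test_that("spearman correlation handles monotone maps and ties", {
  x <- c(0.5, 1.2, 2.1, 3.3, 4.8, 6.1, 7.9)
  expect_equal(spearman_corr(x, x^2)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  # frozen oracle (tied 10-point table; large-sample t approximation)
  s <- spearman_corr(c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7),
                     c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  expect_equal(s$rho, 0.9108770332470622, tolerance = 1e-12)
  expect_equal(s$p, 2.475803237e-04, tolerance = 1e-6)
  # rank-formula oracle: Pearson correlation of average ranks
  set.seed(51)
  a <- sample(1:5, 12, replace = TRUE); b <- sample(1:6, 12, replace = TRUE)
  expect_equal(spearman_corr(a, b)$rho, stats::cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_warning(out <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  # invariance under monotone transforms of either variable
  expect_equal(spearman_corr(exp(a), b)$rho, spearman_corr(a, b)$rho)
})

test_that("roc analysis matches brute-force threshold enumeration", {
  # 6-subject toy set, exhaustive oracle over every cutoff
  scores <- c(3.1, 4.5, 5.0, 6.2, 6.9, 8.0)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)  # low = positive
  r <- roc_analysis(scores, labels, "lower_is_positive")
  cand <- sort(unique(c(scores - 0.01, scores + 0.01)))
  accs <- vapply(cand, function(ct)
    mean((scores < ct) == labels), 0)
  expect_equal(r$accuracy, 100 * max(accs), tolerance = 1e-9)
  # AUC oracle: Mann-Whitney statistic
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  expect_equal(r$auc, mean(cmp), tolerance = 1e-12)
  # the reported operating point reproduces its own confusion matrix
  pred <- scores < r$cutoff
  expect_equal(r$sensitivity, 100 * sum(pred & labels) / sum(labels))
  expect_equal(r$specificity, 100 * sum(!pred & !labels) / sum(!labels))
})

test_that("roc agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (rep in 1:5) {
    sc <- round(rnorm(40), 1)   # ties included
    lb <- rbinom(40, 1, 0.4) == 1
    if (!any(lb) || all(lb)) next
    mine <- roc_analysis(sc, lb, "higher_is_positive")
    ref <- suppressMessages(pROC::roc(lb, sc, direction = "<"))
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  }
})

test_that("roc is invariant to monotone transforms and flips with direction", {
  set.seed(53)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5) == 1
  lb[1:2] <- c(TRUE, FALSE)
  a1 <- roc_analysis(sc, lb, "higher_is_positive")$auc
  a2 <- roc_analysis(exp(sc), lb, "higher_is_positive")$auc
  a3 <- roc_analysis(sc, lb, "lower_is_positive")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a3, 1 - a1, tolerance = 1e-12)
  expect_error(roc_analysis(sc, rep(TRUE, 30)), "both classes")
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    "lower_is_positive")
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 100)
})

test_that("bland-altman reproduces the hand formula", {
  expect_equal(bland_altman(1:5, 1:5),
               list(bias = 0, loa_low = 0, loa_high = 0, sd_diff = 0, n = 5L))
  b <- bland_altman(c(2, 4, 6), c(3, 5, 7))
  expect_equal(b$bias, 1)
  expect_equal(b$loa_low, 1); expect_equal(b$loa_high, 1)
  set.seed(54)
  x <- rnorm(20); y <- x + rnorm(20, 0.3, 0.5)
  b2 <- bland_altman(x, y)
  d <- y - x
  expect_equal(b2$bias, mean(d), tolerance = 1e-12)
  expect_equal(b2$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("icc matches the frozen two-way absolute-agreement oracle", {
  # frozen oracle values computed once with an independent implementation
  x1 <- c(7.7, 5.2, 6.8, 9.1, 4.4, 8.3, 6.1, 7.0, 5.9, 8.8)
  x2 <- c(7.4, 5.6, 6.5, 9.4, 4.9, 8.0, 6.6, 7.2, 5.5, 9.0)
  r <- icc_agreement(x1, x2)
  expect_equal(r$icc, 0.972850, tolerance = 1e-5)
  expect_equal(round(r$ci_low, 2), 0.90)
  expect_equal(round(r$ci_high, 2), 0.99)
  # explicit ANOVA mean-squares oracle on a second table
  set.seed(55)
  y1 <- rnorm(12, 10, 2); y2 <- y1 + rnorm(12, 0.4, 0.8)
  long <- data.frame(y = c(y1, y2),
                     subj = factor(rep(1:12, 2)),
                     rater = factor(rep(1:2, each = 12)))
  ms <- anova(stats::aov(y ~ subj + rater, data = long))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 12)
  expect_equal(icc_agreement(y1, y2)$icc, oracle, tolerance = 1e-10)
  # identical raters
  expect_equal(icc_agreement(y1, y1)$icc, 1)
  expect_warning(icc_agreement(rep(1, 6), rep(1, 6)), "undefined")
})

test_that("icc of independent noise is near zero at large n", {
  set.seed(56)
  r <- icc_agreement(rnorm(500), rnorm(500))
  expect_lt(abs(r$icc), 0.1)
})

test_that("dysfunction labeling applies the guideline thresholds", {
  lab <- label_dysfunction(e_prime_septal = c(9, 7, 9, 9),
                           e_prime_lateral = c(12, 12, 9, 12),
                           la_volume_index = c(20, 20, 20, 40))
  expect_equal(lab, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(label_dysfunction(9, 12), FALSE)
})

test_that("cohort_report wires correlations and classification together", {
  set.seed(57)
  n <- 40
  dys <- rep(c(FALSE, TRUE), each = n / 2)
  psr_ratio <- ifelse(dys, rnorm(n, 0.9, 0.3), rnorm(n, 1.8, 0.5))
  subjects <- data.frame(
    psr_e = ifelse(dys, rnorm(n, 5.2, 1.2), rnorm(n, 7.7, 1.5)),
    psr_ratio = psr_ratio,
    dt_sv_ms = ifelse(dys, rnorm(n, 144, 40), rnorm(n, 96, 30)),
    dsvrt50_pct_rr = ifelse(dys, rnorm(n, 25, 8), rnorm(n, 16, 4)),
    e_prime_septal = pmax(2, 4 * psr_ratio + rnorm(n, 0, 0.8)),
    a_prime_septal = rep(8, n),
    e_prime_lateral = pmax(2, 5 * psr_ratio + rnorm(n, 0, 1)),
    a_prime_lateral = rep(9, n),
    dysfunction = dys)
  rep_ <- cohort_report(subjects)
  expect_gt(rep_$correlations$psr_ratio_vs_septal$rho, 0.8)
  expect_gt(rep_$roc$psr_e$auc, 0.7)
  expect_named(rep_$roc, c("psr_e", "psr_ratio", "dt_sv_ms",
                           "dsvrt50_pct_rr"))
})
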