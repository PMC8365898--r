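test_that("paired t matches the closed-form df = 2 tail and t.test", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, sqrt(12), tolerance = 1e-4)  # 3.4641
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  # closed form for df = 2: p = 1 - |t| / sqrt(2 + t^2)
  expect_equal(res$p_value, 1 - abs(res$statistic) / sqrt(2 + res$statistic^2),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0742)
  ref <- t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # antisymmetry
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  a <- paired_t(x, y); b <- paired_t(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(paired_t(x, x), class = "vm_degenerate_differences")
})

test_that("exact Wilcoxon signed-rank p equals full sign enumeration", {
  res <- wilcoxon_signed_rank(1:5, rep(0, 5))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.0625, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), class = "vm_degenerate_differences")
  set.seed(13)
  for (k in 1:40) {
    m <- sample(3:12, 1)
    x <- round(rnorm(m, 0, 2), 1)  # rounding induces ties and zeros
    y <- round(rnorm(m, 0.5, 2), 1)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
  # tie/zero-free case cross-checked against the standard implementation
  x <- c(1.3, -0.4, 2.2, 0.7, -1.9, 3.1, 0.2, -2.6)
  ref <- wilcox.test(x, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(x, rep(0, 8))$p_value, ref$p.value,
               tolerance = 1e-12)
  # large-sample branch returns a sane approximate p
  set.seed(2)
  big <- wilcoxon_signed_rank(rnorm(40, 0.3), rnorm(40))
  expect_false(big$exact)
  expect_true(big$p_value > 0 && big$p_value < 1)
})

test_that("Shapiro-Wilk wrapper behaves on the contract cases", {
  n <- 20
  scores <- qnorm(((1:n) - 3 / 8) / (n + 1 / 4))
  expect_gt(shapiro_wilk(scores)$statistic, 0.99)
  expect_lt(shapiro_wilk(c(1, 1, 1, 2, 3, 50, 400, 3000))$p_value, 0.05)
  expect_error(shapiro_wilk(c(5, 5, 5, 5)), class = "vm_zero_variance")
})

test_that("paired-comparison routing is driven by normality of differences", {
  set.seed(8)
  base <- rnorm(20, 10, 1)
  normal_diff <- compare_paired(base + rnorm(20, 0.2, 0.5), base)
  expect_identical(normal_diff$test_used, "paired_t")
  expect_gte(normal_diff$shapiro_p, 0.05)
  skewed <- base + c(rep(0.01, 17), 8, 12, 20)
  skew_cmp <- compare_paired(skewed, base)
  expect_identical(skew_cmp$test_used, "wilcoxon")
  expect_lt(skew_cmp$shapiro_p, 0.05)
  # routing is a pure function of the Shapiro p of the differences
  for (k in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    cmp <- compare_paired(x, y)
    expect_identical(cmp$test_used,
                     if (shapiro_wilk(x - y)$p_value >= 0.05) "paired_t" else "wilcoxon")
    expect_identical(cmp$significant, cmp$p_value < 0.05)
  }
  deg <- compare_paired(base, base)
  expect_true(deg$degenerate)
  expect_identical(deg$test_used, "degenerate")
  expect_true(is.na(deg$p_value))
})

test_that("ICC(2,1) matches the hand-worked ANOVA decomposition", {
  m <- matrix(1:8, ncol = 2, byrow = TRUE)  # rows (1,2),(3,4),(5,6),(7,8)
  expect_equal(icc(m), 40 / 3 / (40 / 3 + 1), tolerance = 1e-12)
  expect_equal(icc(m), 0.9302, tolerance = 1e-4)
  # identical columns agree perfectly
  expect_equal(icc(cbind(1:4, 1:4)), 1)
  expect_error(icc(matrix(2, 3, 2)), class = "vm_degenerate_ratings")
  # independent oracle: variance components from aov()
  set.seed(19)
  mm <- matrix(rnorm(24, 10, 2), 8, 3) + rnorm(8, 0, 3)
  df <- data.frame(y = as.vector(mm),
                   subj = factor(rep(1:8, 3)), rater = factor(rep(1:3, each = 8)))
  ms <- summary(aov(y ~ subj + rater, df))[[1]]$`Mean Sq`
  k <- 3; n <- 8
  ref <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  expect_equal(icc(mm), ref, tolerance = 1e-9)
  expect_equal(icc(mm, "icc3_1"), (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3]),
               tolerance = 1e-9)
})

test_that("ICC invariances and the absolute-vs-consistency ordering hold", {
  set.seed(23)
  m <- matrix(rnorm(20, 5, 2), 10, 2) + rnorm(10, 0, 2)
  expect_equal(icc(m + 100), icc(m), tolerance = 1e-9)
  expect_equal(icc(m * 3.5), icc(m), tolerance = 1e-9)
  # constant rater offset: absolute agreement is penalized, consistency is not
  biased <- m; biased[, 2] <- biased[, 2] + 4
  expect_lt(icc(biased), icc(biased, "icc3_1"))
  expect_equal(icc(biased, "icc3_1"), icc(m, "icc3_1"), tolerance = 1e-9)
})

test_that("the excellence threshold is strictly above 0.75", {
  expect_identical(icc_class(0.76), "excellent")
  expect_identical(icc_class(0.75), "below_excellent")
  expect_identical(icc_class(c(0.9, 0.2)), c("excellent", "below_excellent"))
})

test_that("reliability report has the level x dimension layout and routing", {
  d <- study_design(n_subjects = 24, sigma2_subject = 4, sigma2_rater = 0.1,
                    sigma2_error = 0.5, seed = 6)
  dat <- simulate_measurement_study(d, mode = "variance_components")
  tab <- reliability_report(dat)
  expect_s3_class(tab, "vm_reliability_table")
  expect_identical(nrow(tab), 45L)  # 5 levels x 9 dimensions
  expect_setequal(unique(tab$level), c("C3", "C4", "C5", "C6", "C7"))
  expect_identical(length(unique(tab$dimension)), 9L)
  expect_true(all(tab$intra_test %in% c("paired_t", "wilcoxon")))
  expect_true(all(tab$intra_icc <= 1 & tab$inter_icc <= 1))
  expect_identical(tab$intra_icc_class, icc_class(tab$intra_icc))
  expect_error(reliability_report(dat[dat$session != "O2", ]),
               class = "vm_incomplete_design")
})

test_that("a noise-free study yields perfect agreement flagged degenerate", {
  d <- study_design(n_subjects = 6, levels = "C5", sigma2_subject = 4,
                    sigma2_rater = 0, sigma2_error = 0, seed = 2)
  dat <- simulate_measurement_study(d, mode = "variance_components")
  tab <- reliability_report(dat)
  expect_true(all(tab$intra_icc == 1))
  expect_true(all(tab$inter_icc == 1))
  expect_true(all(tab$intra_test == "degenerate"))
  expect_true(all(is.na(tab$intra_p)))
})

test_that("simulated variance components are recovered by the report ICC", {
  d <- study_design(n_subjects = 200, levels = "C5", sigma2_subject = 4,
                    sigma2_rater = 0, sigma2_error = 1, seed = 17)
  dat <- simulate_measurement_study(d, mode = "variance_components")
  tab <- reliability_report(dat)
  expect_equal(mean(c(tab$intra_icc, tab$inter_icc)), theoretical_icc(d),
               tolerance = 0.05)
})
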