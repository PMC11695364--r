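test_that("group comparison picks the test by normality and detects effects", {
  set.seed(15)
  a <- stats::rnorm(50); b <- stats::rnorm(50, mean = 3)
  r <- compare_feature(a, b)
  expect_identical(r$test, "t")
  expect_lt(r$p_value, 0.001)
  # identical groups: no effect
  r0 <- compare_feature(a, a)
  expect_gt(r0$p_value, 0.99)
  # a log-normal group routes to Mann-Whitney
  ln <- exp(stats::rnorm(60, sd = 1.5))
  r2 <- compare_feature(ln, stats::rnorm(60))
  expect_identical(r2$test, "mann_whitney")
  # both constant: flagged p = 1
  r3 <- compare_feature(rep(2, 5), rep(2, 6))
  expect_true(r3$constant)
  expect_identical(r3$p_value, 1)
  expect_error(compare_feature(1:2, 1:5))
})

test_that("summaries follow the mean+-SD / median(Q1-Q3) convention", {
  set.seed(16)
  a <- stats::rnorm(40); b <- stats::rnorm(40, 1)
  r <- compare_feature(a, b)
  expect_match(r$summary_a, "±")
  ln <- exp(stats::rnorm(40, sd = 2))
  r2 <- compare_feature(ln, a)
  expect_match(r2$summary_a, "\\(.*-.*\\)")
})

test_that("AUC equals the Mann-Whitney statistic exhaustively for small n", {
  # identity oracle: AUC = U / (n1 n2), U counting pos > neg pairs with
  # half-credit for ties; exhausted over all label assignments of a value
  # vector that includes ties, n <= 6
  vals <- c(1, 2, 2, 3, 4, 5)
  n <- length(vals)
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code)[1:n])
    if (sum(lab) == 0 || sum(lab) == n) next
    pos <- vals[lab == 1]; neg <- vals[lab == 0]
    u <- sum(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    oracle <- u / (length(pos) * length(neg))
    r <- roc_analysis(vals, factor(lab, levels = c(0, 1)), positive = "1")
    expect_equal(r$auc, oracle, tolerance = 1e-12)
  }
})

test_that("ROC handles separation, orientation, and input validation", {
  set.seed(17)
  pos <- stats::rnorm(20, 5); neg <- stats::rnorm(20)
  lab <- factor(rep(c("n", "p"), each = 20), levels = c("n", "p"))
  r <- roc_analysis(c(neg, pos), lab, positive = "p")
  expect_identical(r$auc, 1)
  expect_identical(r$sensitivity_pct, 100)
  expect_identical(r$specificity_pct, 100)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  # fixed orientation: an anti-predictive feature scores below 0.5
  r2 <- roc_analysis(-c(neg, pos), lab, positive = "p")
  expect_identical(r2$auc, 0)
  expect_error(roc_analysis(pos, rep("p", 20)), "two classes")
  # confusion counts reproduce the reported sensitivity/specificity
  set.seed(18)
  x <- stats::rnorm(60); l <- factor(rep(c("a", "b"), 30))
  x[l == "b"] <- x[l == "b"] + 1
  r3 <- roc_analysis(x, l, positive = "b")
  cm <- confusion_metrics(r3$counts$tp, r3$counts$fn, r3$counts$tn,
                          r3$counts$fp)
  expect_equal(cm$sensitivity_pct, r3$sensitivity_pct)
  expect_equal(cm$specificity_pct, r3$specificity_pct)
})

test_that("confusion arithmetic reproduces printed %(k/n) cells", {
  expect_equal(confusion_metrics(20, 4, 9, 7)$sensitivity_pct, 83.33)
  expect_equal(confusion_metrics(13, 11, 15, 1)$specificity_pct, 93.75)
  expect_equal(confusion_metrics(10, 0, 5, 0)$sensitivity_pct, 100)
  expect_identical(format_pct_counts(20, 24), "83.33% (20/24)")
  expect_error(confusion_metrics(0, 0, 5, 5), "denominator")
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
  expect_error(confusion_metrics(1.5, 2, 3, 4), "non-negative")
})

test_that("collinearity screen matches the closed-form VIF oracle", {
  set.seed(19)
  n <- 80
  ortho <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  s0 <- collinearity_screen(ortho)
  expect_identical(s0$retained, c("a", "b", "c"))
  expect_true(all(abs(s0$vif - 1) < 0.2))
  # three equicorrelated features, rho = 0.95: VIF = 1 / (1 - R^2) with R^2
  # from an independent regression oracle
  z <- stats::rnorm(n)
  x <- sapply(1:3, function(i) sqrt(0.95) * z + sqrt(0.05) * stats::rnorm(n))
  colnames(x) <- c("f1", "f2", "f3")
  vif_pkg <- collinearity_screen(x, vif_max = Inf, tol_min = 0)$vif
  oracle <- sapply(1:3, function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j]))$r.squared
    1 / (1 - r2)
  })
  expect_equal(unname(vif_pkg), oracle, tolerance = 1e-8)
  # exact duplicate: the later-listed one is dropped with a warning
  dup <- cbind(ortho, a2 = ortho[, "a"])
  expect_warning(s1 <- collinearity_screen(dup), "collinear")
  expect_identical(s1$dropped, "a2")
  expect_error(collinearity_screen(ortho[1:3, ]), "more subjects")
})

test_that("combined logistic model behaves like nested models should", {
  set.seed(20)
  n <- 120
  strong <- c(stats::rnorm(n / 2), stats::rnorm(n / 2, 2))
  weak <- stats::rnorm(n)
  lab <- factor(rep(c("lo", "hi"), each = n / 2), levels = c("lo", "hi"))
  single <- roc_analysis(strong, lab, positive = "hi")
  comb <- fit_combined_model(cbind(strong = strong, weak = weak), lab,
                             positive = "hi")
  # logistic regression maximizes likelihood, not AUC, so adding a noise
  # feature can cost a hairline of apparent AUC; anything beyond that
  # indicates a broken fit
  expect_gte(comb$roc$auc + 0.005, single$auc)
  # shuffled labels: chance-level in-sample AUC on large n (apparent
  # performance still slightly optimistic, so allow a band around 0.5)
  sh <- sample(lab)
  comb0 <- fit_combined_model(cbind(strong = strong, weak = weak), sh,
                              positive = "hi")
  expect_lt(abs(comb0$roc$auc - 0.5), 0.12)
  # two complementary independent features beat either alone
  f1 <- c(stats::rnorm(n / 2), stats::rnorm(n / 2, 1.05))
  f2 <- c(stats::rnorm(n / 2), stats::rnorm(n / 2, 1.05))
  a1 <- roc_analysis(f1, lab, positive = "hi")$auc
  a2 <- roc_analysis(f2, lab, positive = "hi")$auc
  both <- fit_combined_model(cbind(f1 = f1, f2 = f2), lab, positive = "hi")
  expect_gt(both$roc$auc, max(a1, a2))
})

test_that("separated data falls back to a ridge-stabilized fit", {
  x <- c(1:10, 21:30)
  lab <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  expect_warning(m <- fit_combined_model(cbind(x = x), lab, positive = "b",
                                         screen = FALSE), "separation")
  expect_true(m$separation)
  expect_identical(m$roc$auc, 1)
  expect_true(is.finite(m$coefficients["x"]))
})

test_that("ICC(A,1) matches trivial cases and a variance-component oracle", {
  set.seed(22)
  x <- stats::rnorm(30, 10, 3)
  same <- icc_interobserver(x, x)
  expect_equal(same$icc, 1, tolerance = 1e-12)
  noisy <- icc_interobserver(x, stats::rnorm(30, 10, 50))
  expect_lt(abs(noisy$icc), 0.35)
  # oracle: subjects sigma_s^2 = 9, rater shift sigma_c^2 ~ 0.25,
  # error sigma_e^2 = 1 -> ICC = 9 / (9 + 0.25 + 1) ~ 0.878
  n <- 400
  subj <- stats::rnorm(n, 0, 3)
  bias <- c(0, 1) * 0.5 * sqrt(2)   # two raters, sd 0.5 between columns
  r1 <- subj + bias[1] + stats::rnorm(n)
  r2 <- subj + bias[2] + stats::rnorm(n)
  est <- icc_interobserver(r1, r2)
  oracle <- 9 / (9 + 0.25 + 1)
  expect_true(est$ci_low <= oracle && oracle <= est$ci_high)
  expect_equal(est$icc, oracle, tolerance = 0.08)
  # zero variance is flagged undefined
  flat <- icc_interobserver(rep(1, 6), rep(1, 6))
  expect_true(flat$undefined)
})
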