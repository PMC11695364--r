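#' Two-group comparison with normality-adaptive test choice
#'
#' Assesses normality in each group with the Shapiro-Wilk test at
#' `alpha_normality`; if both groups look normal an independent-samples
#' t-test (pooled variance) is used and the groups are summarized as
#' mean +/- SD, otherwise a Mann-Whitney U test is used with
#' median (Q1-Q3) summaries. A feature constant in both groups yields
#' `p = 1` with a flag.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param feature Name recorded in the result.
#' @param alpha_normality Shapiro-Wilk significance level.
#' @return An object of class `comparison_result`: `feature`, `test`
#'   (`"t"`, `"mann_whitney"` or `"none"`), `statistic`, `p_value`,
#'   `normal`, `summary_a`, `summary_b`, `constant` flag.
#' @export
compare_feature <- function(values_a, values_b, feature = "feature",
                            alpha_normality = 0.05) {
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  summarize <- function(v, normal) {
    if (normal) sprintf("%.4g ± %.4g", mean(v), stats::sd(v))
    else {
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      sprintf("%.4g (%.4g-%.4g)", stats::median(v), q[1], q[2])
    }
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    return(structure(
      list(feature = feature, test = "none", statistic = NA_real_,
           p_value = 1, normal = NA,
           summary_a = summarize(values_a, FALSE),
           summary_b = summarize(values_b, FALSE), constant = TRUE),
      class = "comparison_result"))
  }
  shapiro_ok <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  normal <- shapiro_ok(values_a) && shapiro_ok(values_b)
  if (normal) {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(values_a, values_b, exact = FALSE)
    test <- "mann_whitney"
  }
  structure(
    list(feature = feature, test = test,
         statistic = unname(ht$statistic), p_value = ht$p.value,
         normal = normal, summary_a = summarize(values_a, normal),
         summary_b = summarize(values_b, normal), constant = FALSE),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s, %s test, p = %.4g\n", x$feature, x$summary_a,
              x$summary_b, x$test, x$p_value))
  invisible(x)
}

#' ROC analysis with DeLong interval and Youden cutoff
#'
#' Computes the empirical AUC of a feature against binary labels, a
#' confidence interval (DeLong by default, bootstrap optionally), the
#' optimal cutoff by Youden's J, and the confusion counts with sensitivity
#' and specificity at that cutoff. The orientation is fixed
#' (`direction = "<"`: the positive class is expected to take larger
#' values, and the AUC equals the probability a positive exceeds a
#' negative, so an anti-predictive feature yields AUC below 0.5); pass
#' `direction = "auto"` to always report the better-oriented AUC.
#'
#' @param values Numeric feature values.
#' @param labels Binary labels (factor/character/logical); `positive` names
#'   the positive class (defaults to the second factor level).
#' @param positive Positive class label.
#' @param direction `"<"` (fixed, default), `">"`, or `"auto"`.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param conf Confidence level.
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity_pct`, `specificity_pct`, `counts`
#'   (tp/fn/tn/fp), `n_pos`, `n_neg`, `direction`, and the underlying pROC
#'   object `roc`.
#' @export
roc_analysis <- function(values, labels, positive = NULL, direction = "<",
                         ci_method = c("delong", "bootstrap"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  negative <- setdiff(levels(labels), positive)
  if (length(negative) != 1L) stop("positive class not found in labels")
  r <- pROC::roc(response = labels, predictor = values,
                 levels = c(negative, positive), direction = direction,
                 quiet = TRUE)
  ci <- suppressWarnings(if (ci_method == "delong") {
    pROC::ci.auc(r, conf.level = conf, method = "delong")
  } else {
    pROC::ci.auc(r, conf.level = conf, method = "bootstrap", boot.n = 2000,
                 progress = "none")
  })
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity",
                               "tp", "fp", "tn", "fn"),
                       transpose = FALSE)
  if (nrow(best) > 1L) best <- best[1, , drop = FALSE]
  counts <- list(tp = best$tp, fn = best$fn, tn = best$tn, fp = best$fp)
  structure(
    list(auc = as.numeric(pROC::auc(r)),
         ci_low = ci[1], ci_high = ci[3],
         cutoff = best$threshold,
         sensitivity_pct = round(100 * best$sensitivity, 2),
         specificity_pct = round(100 * best$specificity, 2),
         counts = counts, n_pos = sum(labels == positive),
         n_neg = sum(labels == negative),
         direction = r$direction, roc = r),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.2f (%.2f-%.2f), cutoff %.4g, sens %s, spec %s\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff,
    format_pct_counts(x$counts$tp, x$counts$tp + x$counts$fn),
    format_pct_counts(x$counts$tn, x$counts$tn + x$counts$fp)))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = 100 * tp / (tp + fn)` and
#' `specificity = 100 * tn / (tn + fp)`, rounded to two decimals for report
#' formatting (the "% (k/n)" convention of diagnostic tables).
#'
#' @param tp,fn,tn,fp Non-negative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return List with `sensitivity_pct` and `specificity_pct`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("confusion counts give a zero denominator")
  }
  list(sensitivity_pct = round(100 * tp / (tp + fn), 2),
       specificity_pct = round(100 * tn / (tn + fp), 2))
}

#' @rdname confusion_metrics
#' @param k,n Numerator and denominator of a printed "% (k/n)" cell.
#' @export
format_pct_counts <- function(k, n) {
  sprintf("%.2f%% (%d/%d)", 100 * k / n, k, n)
}

#' Collinearity screen by tolerance and VIF
#'
#' Computes each feature's variance inflation factor by regressing it on
#' all other features (`VIF = 1 / (1 - R^2)`, tolerance `= 1/VIF`) and
#' iteratively drops the worst feature violating `Tol < tol_min` or
#' `VIF > vif_max` (greedy: drop, recompute, repeat) until all remaining
#' features pass. A perfectly collinear pair gives infinite VIF; the
#' later-listed member is dropped with a warning.
#'
#' @param feature_matrix Numeric matrix or data.frame (subjects x features).
#' @param tol_min Minimum tolerance.
#' @param vif_max Maximum VIF.
#' @return List with `retained`, `dropped`, `vif`, `tolerance` (final
#'   values, named by feature).
#' @export
collinearity_screen <- function(feature_matrix, tol_min = 0.1,
                                vif_max = 10) {
  x <- as.matrix(feature_matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) <= ncol(x) + 1L) {
    stop("need more subjects than features + 1 for the collinearity screen")
  }
  vif_of <- function(m) {
    if (ncol(m) < 2L) return(stats::setNames(rep(1, ncol(m)), colnames(m)))
    vapply(seq_len(ncol(m)), function(j) {
      fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((m[, j] - mean(m[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(m))
  }
  dropped <- character(0)
  repeat {
    v <- vif_of(x)
    bad <- which(v > vif_max | (1 / v) < tol_min)
    if (length(bad) == 0L) break
    worst <- bad[which.max(v[bad])]
    if (length(bad) > 1L && sum(v[bad] == v[worst]) > 1L) {
      worst <- max(bad[v[bad] == max(v[bad])])  # tie: drop later-listed
    }
    if (is.infinite(v[worst])) {
      warning(sprintf("feature '%s' is perfectly collinear; dropped",
                      colnames(x)[worst]))
    }
    dropped <- c(dropped, colnames(x)[worst])
    x <- x[, -worst, drop = FALSE]
    if (ncol(x) == 0L) break
  }
  v <- if (ncol(x) > 0L) vif_of(x) else numeric(0)
  list(retained = colnames(x), dropped = dropped, vif = v,
       tolerance = 1 / v)
}

#' Combined logistic model over screened features
#'
#' Screens the features for collinearity, fits a binary logistic regression
#' by maximum likelihood, and evaluates the in-sample (apparent) ROC of the
#' predicted probabilities — no cross-validation is performed, so the AUC
#' is optimistic, which is reported as a field and documented. If complete
#' or quasi-complete separation is detected the fit falls back to a
#' ridge-stabilized logistic regression with a warning.
#'
#' @param feature_matrix Numeric matrix/data.frame (subjects x features).
#' @param labels Binary labels.
#' @param positive Positive class label.
#' @param screen Run [collinearity_screen()] first (default `TRUE`).
#' @param ridge_lambda L2 penalty used by the separation fallback.
#' @return An object of class `combined_model`: `coefficients`,
#'   `intercept`, `retained`, `screen` diagnostics, `separation` flag,
#'   `fitted_prob`, and `roc` (a [roc_analysis()] result on the in-sample
#'   probabilities).
#' @export
fit_combined_model <- function(feature_matrix, labels, positive = NULL,
                               screen = TRUE, ridge_lambda = 0.1) {
  x <- as.matrix(feature_matrix)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  y <- as.integer(labels == positive)
  scr <- if (screen) collinearity_screen(x) else
    list(retained = colnames(x), dropped = character(0))
  x <- x[, scr$retained, drop = FALSE]
  df <- data.frame(y = y, x)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warning("separation detected; using ridge-stabilized logistic fit")
    xs <- scale(x)
    beta <- stats::setNames(rep(0, ncol(xs) + 1L), c("(Intercept)", colnames(x)))
    # IRLS with an L2 penalty on the standardized slopes
    b <- rep(0, ncol(xs) + 1L)
    X <- cbind(1, xs)
    for (it in 1:100) {
      eta <- drop(X %*% b)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-8)
      zz <- eta + (y - mu) / w
      P <- diag(c(0, rep(ridge_lambda, ncol(xs))))
      bn <- solve(crossprod(X, w * X) + P, crossprod(X, w * zz))
      if (max(abs(bn - b)) < 1e-10) { b <- bn; break }
      b <- bn
    }
    prob <- stats::plogis(drop(X %*% b))
    # map standardized slopes back to the raw feature scale
    sds <- attr(xs, "scaled:scale"); mns <- attr(xs, "scaled:center")
    slopes <- drop(b[-1]) / sds
    beta[] <- c(b[1] - sum(slopes * mns), slopes)
    coefs <- beta
  } else {
    coefs <- stats::coef(fit)
    prob <- stats::fitted(fit)
  }
  roc <- roc_analysis(prob, labels, positive = positive, direction = "<")
  structure(
    list(coefficients = coefs[-1], intercept = unname(coefs[1]),
         retained = scr$retained, screen = scr, separation = separation,
         fitted_prob = prob, roc = roc, in_sample = TRUE),
    class = "combined_model"
  )
}

#' Inter-observer intraclass correlation
#'
#' ICC(A,1): two-way random effects, absolute agreement, single measure —
#' the standard choice for two raters measuring the same subjects once.
#' Computed from the ANOVA mean squares with the McGraw-Wong confidence
#' interval. Zero variance across subjects and raters leaves the ICC
#' undefined (`NA`, flagged).
#'
#' @param measurements_rater1,measurements_rater2 Paired numeric vectors
#'   (length >= 5).
#' @param conf Confidence level.
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, `k`, `undefined`.
#' @export
icc_interobserver <- function(measurements_rater1, measurements_rater2,
                              conf = 0.95) {
  x <- cbind(measurements_rater1, measurements_rater2)
  stopifnot(nrow(x) >= 5L, !anyNA(x))
  n <- nrow(x); k <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, k = k, undefined = TRUE))
  }
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    return(list(icc = icc, ci_low = icc, ci_high = icc, n = n, k = k,
                undefined = FALSE))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = low, ci_high = high, n = n, k = k,
       undefined = FALSE)
}
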