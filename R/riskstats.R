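# Diagnostic-model statistics: group comparisons from raw data or printed
# summaries, univariate screening, and forward-stepwise logistic regression
# with likelihood-ratio entry tests.

#' Two-sample t-test from group summaries
#'
#' Computes the independent-samples t-test directly from per-group mean, SD
#' and n. The default is the Welch (unequal-variance) test with
#' Satterthwaite degrees of freedom; `variant = "pooled"` gives the
#' equal-variance test.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' welch_t_from_summary(320.28, 26.79, 31, 301.32, 35.42, 28)$p  # ~0.026
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stop_if(n1 < 2 || n2 < 2, "each group needs n >= 2")
  stop_if(sd1 <= 0 || sd2 <= 0, "SDs must be positive")
  if (variant == "welch") {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability definition: the p-value sums hypergeometric
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed table's.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(1, 27, 9, 22), 2, byrow = TRUE))  # ~0.013
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stop_if(any(dim(tab) != 2), "table must be 2x2")
  stop_if(any(tab < 0) || any(tab != round(tab)), "counts must be non-negative integers")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The returned `U` counts pairs where an `x`
#' observation exceeds a `y` observation (+ 1/2 per tie), so
#' `U / (n1 * n2)` is the empirical probability that `x > y` -- identically
#' the ROC AUC of `x` against `y`.
#'
#' @param x,y Numeric samples.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  stop_if(length(x) < 1 || length(y) < 1, "both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Chi-square test with automatic exact-test routing
#'
#' Yates-corrected chi-square on a 2x2 table; when any expected cell count
#' falls below 5, the test routes to [fisher_exact()] (reported in the
#' `method` field).
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `statistic` (NA when routed to Fisher), `p`, `method`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  stop_if(any(dim(tab) != 2), "table must be 2x2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    return(list(statistic = NA_real_, p = fisher_exact(tab),
                method = "fisher"))
  }
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ct$statistic), p = ct$p.value,
       method = "chi-square")
}

#' Univariate screening of candidate predictors
#'
#' Tests each candidate against the binary outcome: Welch t-test for
#' continuous variables, Fisher exact test for binary ones. Variables with
#' `p < alpha_in` (default 0.1) pass the screen; constant columns are
#' excluded with a warning.
#'
#' @param cohort Data frame with an outcome column and candidate columns.
#' @param candidates Character vector of candidate column names.
#' @param outcome Name of the outcome column (two levels; the second sorted
#'   level, or 1, is the positive class).
#' @param alpha_in Screening threshold on the univariate p-value.
#' @return Data frame with `variable`, `p`, `test`, `selected`; attribute
#'   `selected` carries the passing variable names.
#' @export
univariate_screen <- function(cohort,
                              candidates = c("lvet_ms", "q2s2max",
                                             "htn_history", "hr_bpm"),
                              outcome = "group", alpha_in = 0.1) {
  y <- outcome_to_binary(cohort[[outcome]])
  res <- lapply(candidates, function(v) {
    x <- cohort[[v]]
    if (length(unique(x)) < 2) {
      warning(sprintf("candidate '%s' is constant; excluded", v))
      return(data.frame(variable = v, p = NA_real_, test = "none"))
    }
    if (length(unique(x)) == 2) {
      tab <- table(factor(x), factor(y, levels = c(0, 1)))
      data.frame(variable = v, p = fisher_exact(tab), test = "fisher")
    } else {
      tt <- stats::t.test(x[y == 1], x[y == 0])
      data.frame(variable = v, p = tt$p.value, test = "welch-t")
    }
  })
  res <- do.call(rbind, res)
  res$selected <- !is.na(res$p) & res$p < alpha_in
  attr(res, "selected") <- res$variable[res$selected]
  res
}

outcome_to_binary <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) return(y)
  f <- factor(y)
  stop_if(nlevels(f) != 2, "outcome must have exactly two levels")
  as.integer(f == levels(f)[2])
}

#' Forward-stepwise logistic regression by likelihood-ratio entry
#'
#' Starting from the intercept-only model, at each step the candidate whose
#' addition gives the smallest likelihood-ratio p-value enters if that
#' p-value is below `alpha_enter` (default 0.05); the procedure stops when
#' no candidate qualifies. Coefficients are reported as odds ratios with
#' Wald 95% confidence intervals. Complete separation is flagged and the
#' model refit with a small ridge penalty on the affected fit.
#'
#' @param cohort Data frame.
#' @param candidates Candidate predictor column names (normally the
#'   survivors of [univariate_screen()]).
#' @param outcome Outcome column name.
#' @param alpha_enter Entry threshold for the LRT p-value.
#' @return An `acg_logistic_model`: `variables`, `coefficients` table
#'   (estimate, OR, CI, p), `fit`, `probabilities` (per-subject predicted
#'   probability of the positive class), `separation` flag, `steps` log.
#' @export
fit_logistic_forward <- function(cohort, candidates, outcome = "group",
                                 alpha_enter = 0.05) {
  stop_if(nrow(cohort) < 10, "need >= 10 subjects")
  y <- outcome_to_binary(cohort[[outcome]])
  dat <- cohort[, intersect(candidates, names(cohort)), drop = FALSE]
  dat$.y <- y

  included <- character(0)
  remaining <- candidates
  steps <- list()
  fit <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  repeat {
    if (length(remaining) == 0) break
    trial <- lapply(remaining, function(v) {
      f <- stats::as.formula(paste(".y ~", paste(c(included, v),
                                                 collapse = " + ")))
      cand <- suppressWarnings(stats::glm(f, data = dat,
                                          family = stats::binomial()))
      lrt <- stats::anova(fit, cand, test = "LRT")
      list(variable = v, fit = cand, p = lrt$`Pr(>Chi)`[2])
    })
    ps <- vapply(trial, function(t) t$p, numeric(1))
    best <- which.min(ps)
    if (!is.finite(ps[best]) || ps[best] >= alpha_enter) break
    fit <- trial[[best]]$fit
    included <- c(included, remaining[best])
    steps[[length(steps) + 1]] <- list(entered = remaining[best],
                                       p = ps[best])
    remaining <- remaining[-best]
  }

  separation <- any(abs(stats::coef(fit)[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separation && length(included) > 0) {
    # small ridge penalty via data augmentation keeps estimates finite
    fit <- ridge_logistic(dat, included)
  }

  cf <- summary(fit)$coefficients
  se <- cf[, 2]
  est <- cf[, 1]
  coefs <- data.frame(term = rownames(cf), estimate = est,
                      odds_ratio = exp(est),
                      or_ci_lo = exp(est - 1.96 * se),
                      or_ci_hi = exp(est + 1.96 * se),
                      p = cf[, 4], row.names = NULL)
  probs <- as.numeric(stats::predict(fit, newdata = dat, type = "response"))
  structure(list(variables = included, coefficients = coefs, fit = fit,
                 probabilities = probs, separation = separation,
                 steps = steps, alpha_enter = alpha_enter),
            class = "acg_logistic_model")
}

# weak ridge by Gaussian pseudo-observations on the coefficients
ridge_logistic <- function(dat, included) {
  f <- stats::as.formula(paste(".y ~", paste(included, collapse = " + ")))
  x <- stats::model.matrix(f, dat)
  aug <- as.data.frame(rbind(x[, -1, drop = FALSE],
                             diag(1e2, length(included))))
  names(aug) <- included
  aug$.y <- c(dat$.y, rep(0.5, length(included)))
  w <- c(rep(1, nrow(dat)), rep(1e-2, length(included)))
  suppressWarnings(stats::glm(f, data = aug, family = stats::binomial(),
                              weights = w))
}

#' @export
print.acg_logistic_model <- function(x, ...) {
  cat("<logistic model>", if (length(x$variables) == 0) "(intercept only)"
      else paste(x$variables, collapse = " + "),
      if (x$separation) "[separation flagged; ridge-penalized]" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
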