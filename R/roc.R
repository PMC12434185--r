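# ROC analysis with Youden-optimal cutoff, DeLong variance for the AUC
# confidence interval, confusion metrics, and the paired DeLong test.

# Midrank-based AUC and DeLong placement values.
# Returns auc, v10 (placements over positives), v01 (over negatives).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  stop_if(m == 0 || n == 0, "both classes must be present")
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = sum(r_all[seq_len(m)] - r_pos) / (m * n), v10 = v10, v01 = v01)
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive values from
#' confusion counts. A zero denominator yields `NA` for the affected metric
#' rather than an error.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` (fractions).
#' @examples
#' confusion_metrics(tp = 22, fp = 12, tn = 16, fn = 9)  # PPV 0.6471, NPV 0.64
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "counts must be non-negative integers")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn))
}

#' ROC analysis with Youden-optimal cutoff and DeLong interval
#'
#' Builds the empirical ROC curve, computes the AUC by the midrank
#' (Mann-Whitney) identity, a DeLong 95% confidence interval, and the
#' Youden-optimal cutoff (maximizing sensitivity + specificity - 1; ties
#' broken toward the lowest cutoff). Positivity is `score >= cutoff` when
#' `positive_direction = "greater"` (e.g., prolonged LVET indicating PE),
#' `score <= cutoff` otherwise.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1 or a two-level factor; second level is
#'   positive).
#' @param positive_direction `"greater"` (default) or `"less"`.
#' @return An `acg_roc` object: `auc`, `auc_ci_95`, `auc_se`, `cutoff`,
#'   confusion metrics and counts at the cutoff, and `curve` (data frame of
#'   cutoff/fpr/tpr points).
#' @export
roc_analysis <- function(scores, labels,
                         positive_direction = c("greater", "less")) {
  positive_direction <- match.arg(positive_direction)
  y <- outcome_to_binary(labels)
  stop_if(length(scores) != length(y), "scores and labels differ in length")
  stop_if(any(!is.finite(scores)), "scores must be finite")
  s <- if (positive_direction == "greater") scores else -scores

  dp <- delong_placements(s, y)
  m <- sum(y == 1); n <- sum(y == 0)
  var_auc <- stats::var(dp$v10) / m + stats::var(dp$v01) / n
  se <- sqrt(max(var_auc, 0))
  z975 <- stats::qnorm(0.975)
  ci <- pmin(pmax(dp$auc + c(-z975, z975) * se, 0), 1)

  # candidate cutoffs on the oriented scale: every observed score
  cand <- sort(unique(s))
  sens <- vapply(cand, function(c) sum(s >= c & y == 1) / m, numeric(1))
  spec <- vapply(cand, function(c) sum(s < c & y == 0) / n, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  # lowest cutoff among maximizers, on the original score scale
  cut_oriented <- cand[best[1]]
  if (positive_direction == "less") {
    cut_oriented <- -cand[best[length(best)]]
  }
  bi <- if (positive_direction == "greater") best[1] else best[length(best)]

  pred_pos <- s >= cand[if (positive_direction == "greater") best[1]
                        else best[length(best)]]
  tp <- sum(pred_pos & y == 1); fp <- sum(pred_pos & y == 0)
  fn <- m - tp; tn <- n - fp
  cm <- confusion_metrics(tp, fp, tn, fn)

  curve <- data.frame(cutoff = if (positive_direction == "greater") cand
                      else rev(-cand),
                      fpr = 1 - spec, tpr = sens)
  curve <- rbind(data.frame(cutoff = NA_real_, fpr = 1, tpr = 1),
                 curve[order(curve$fpr, curve$tpr), ])
  curve <- rbind(curve, data.frame(cutoff = NA_real_, fpr = 0, tpr = 0))
  curve <- curve[order(curve$fpr, curve$tpr), ]

  structure(list(auc = dp$auc, auc_ci_95 = ci, auc_se = se,
                 cutoff = cut_oriented,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 ppv = cm$ppv, npv = cm$npv,
                 counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 youden = j[bi], positive_direction = positive_direction,
                 curve = curve),
            class = "acg_roc")
}

#' @export
print.acg_roc <- function(x, ...) {
  cat(sprintf("<roc> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g (%s)\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$cutoff,
              x$positive_direction))
  cat(sprintf("  sens %.1f%% spec %.1f%% ppv %.1f%% npv %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers evaluated on the same subjects using
#' the DeLong placement-value covariance, giving a two-sided z-test.
#' Higher score = positive for both classifiers.
#'
#' @param scoresA,scoresB Paired classifier scores.
#' @param labels Binary labels shared by both.
#' @return List with `aucA`, `aucB`, `auc_diff`, `se`, `z`, `p`. A
#'   degenerate (zero) variance yields `p = 1` with a warning.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  y <- outcome_to_binary(labels)
  stop_if(length(scoresA) != length(y) || length(scoresB) != length(y),
          "paired predictions must match the labels in length")
  a <- delong_placements(scoresA, y)
  b <- delong_placements(scoresB, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  if (var_diff <= 0) {
    if (abs(diff) > 0) warning("degenerate DeLong variance; p set to 1")
    return(list(aucA = a$auc, aucB = b$auc, auc_diff = diff, se = 0,
                z = 0, p = 1))
  }
  z <- diff / sqrt(var_diff)
  list(aucA = a$auc, aucB = b$auc, auc_diff = diff, se = sqrt(var_diff),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}
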