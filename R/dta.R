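# Diagnostic-test-accuracy machinery: 2x2 cross-tabulation against the HCC
# reference diagnosis, exact binomial intervals, exact McNemar tests, the
# two-point ROC of a binary rule, and the correlated-AUC comparison via
# placement values.

#' Cross-tabulate a positivity rule against the HCC reference diagnosis
#'
#' The truth-positive class is HCC; non-HCC malignancies and benign lesions
#' both count as truth-negative.
#'
#' @param positives logical vector of rule positivity (see [positivity()]).
#' @param truth diagnosis vector (`"HCC"`, `"NON_HCC_MALIGNANCY"`,
#'   `"BENIGN"`) of the same length.
#' @return object of class `confusion_table`: list with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' confusion(c(TRUE, FALSE, TRUE), c("HCC", "HCC", "BENIGN"))
#' @export
confusion <- function(positives, truth) {
  if (length(positives) != length(truth)) {
    stop("positives and truth must have the same length")
  }
  positives <- as.logical(positives)
  pos_truth <- truth == "HCC"
  structure(
    list(
      tp = sum(positives & pos_truth),
      fp = sum(positives & !pos_truth),
      fn = sum(!positives & pos_truth),
      tn = sum(!positives & !pos_truth)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("2x2 table vs HCC truth: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The interval inverts the exact binomial test through the beta-quantile
#' form; the lower bound is 0 when `x = 0` and the upper bound 1 when
#' `x = n`.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (> 0).
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @return matrix with columns `lower` and `upper`, one row per input.
#' @examples
#' clopper_pearson(365, 508)
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(n <= 0)) stop("n must be positive")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  k <- max(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Diagnostic-accuracy metrics with exact intervals for one 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values and overall accuracy with exact Clopper-Pearson intervals, and the
#' two-point ROC AUC of the binary rule with a DeLong-variance normal
#' interval. A metric whose denominator is zero is flagged as undefined
#' (`defined = FALSE`) rather than raising an error.
#'
#' @param ct a `confusion_table` from [confusion()].
#' @param alpha two-sided error rate for all intervals.
#' @param variant optional evaluation label carried into the report.
#' @return object of class `dta_report`: list with `variant`, `metrics` (a
#'   data.frame with one row per metric: numerator, denominator, estimate,
#'   CI bounds and a `defined` flag), `auc`, `auc_ci` and `alpha`.
#' @examples
#' ct <- confusion(c(TRUE, TRUE, FALSE), c("HCC", "BENIGN", "HCC"))
#' dta_metrics(ct)
#' @export
dta_metrics <- function(ct, alpha = 0.05, variant = NA_character_) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$tp + ct$fp + ct$fn + ct$tn
  rows <- list(
    sensitivity = c(ct$tp, ct$tp + ct$fn),
    specificity = c(ct$tn, ct$tn + ct$fp),
    ppv         = c(ct$tp, ct$tp + ct$fp),
    npv         = c(ct$tn, ct$tn + ct$fn),
    accuracy    = c(ct$tp + ct$tn, total)
  )
  metrics <- do.call(rbind, lapply(names(rows), function(name) {
    num <- rows[[name]][1]; den <- rows[[name]][2]
    if (den == 0) {
      data.frame(metric = name, numerator = num, denominator = den,
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 defined = FALSE, stringsAsFactors = FALSE)
    } else {
      ci <- clopper_pearson(num, den, alpha)
      data.frame(metric = name, numerator = num, denominator = den,
                 estimate = num / den, lower = ci[1, "lower"], upper = ci[1, "upper"],
                 defined = TRUE, stringsAsFactors = FALSE)
    }
  }))
  m <- ct$tp + ct$fn
  n <- ct$fp + ct$tn
  if (m > 0 && n > 0) {
    sens <- ct$tp / m
    spec <- ct$tn / n
    auc <- (sens + spec) / 2
    v <- binary_auc_variance(ct)
    z <- qnorm(1 - alpha / 2)
    auc_ci <- c(lower = max(0, auc - z * sqrt(v)), upper = min(1, auc + z * sqrt(v)))
  } else {
    auc <- NA_real_
    auc_ci <- c(lower = NA_real_, upper = NA_real_)
  }
  structure(
    list(variant = variant, metrics = metrics, auc = auc, auc_ci = auc_ci,
         alpha = alpha),
    class = "dta_report"
  )
}

#' @export
print.dta_report <- function(x, digits = 3, ...) {
  if (!is.na(x$variant)) cat("Evaluation:", x$variant, "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (!m$defined[i]) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%d/%d) [%.1f, %.1f]\n",
                  m$metric[i], 100 * m$estimate[i], m$numerator[i],
                  m$denominator[i], 100 * m$lower[i], 100 * m$upper[i]))
    }
  }
  if (!is.na(x$auc)) {
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", "auc", x$auc,
                x$auc_ci["lower"], x$auc_ci["upper"]))
  }
  invisible(x)
}

# DeLong variance of the two-point AUC, in closed form from the counts.
# Placement values of a 0/1 score take only two values in each truth class.
binary_auc_variance <- function(ct) {
  m <- ct$tp + ct$fn
  n <- ct$fp + ct$tn
  v1 <- (ct$tn + 0.5 * ct$fp) / n   # placement of a positive scored 1
  v0 <- 0.5 * ct$tn / n             # placement of a positive scored 0
  auc <- (ct$tp * v1 + ct$fn * v0) / m
  s10 <- if (m > 1) (ct$tp * (v1 - auc)^2 + ct$fn * (v0 - auc)^2) / (m - 1) else 0
  w1 <- 0.5 * ct$tp / m             # placement of a negative scored 1
  w0 <- (ct$tp + 0.5 * ct$fn) / m   # placement of a negative scored 0
  s01 <- if (n > 1) (ct$fp * (w1 - auc)^2 + ct$tn * (w0 - auc)^2) / (n - 1) else 0
  s10 / m + s01 / n
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact binomial test of `b` successes in `b + c` trials at rate
#' 1/2: `p = min(1, 2 * P(X <= min(b, c)))`, with `p = 1` when there are no
#' discordant pairs. The asymptotic chi-square form (without continuity
#' correction) is available as an alternative but is not the default.
#'
#' @param b,c discordant-pair counts (positive-to-negative and
#'   negative-to-positive between two rules within one truth class).
#' @param method `"exact"` (default) or `"asymptotic"`.
#' @return the p-value, a number in (0, 1].
#' @examples
#' mcnemar_exact(3, 0)   # 0.25
#' mcnemar_exact(8, 0)   # 0.0078125
#' @export
mcnemar_exact <- function(b, c, method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0,
            b == round(b), c == round(c))
  if (b + c == 0) return(1)
  if (method == "exact") {
    min(1, 2 * pbinom(min(b, c), b + c, 0.5))
  } else {
    stat <- (b - c)^2 / (b + c)
    max(pchisq(stat, df = 1, lower.tail = FALSE), .Machine$double.xmin)
  }
}

#' Two-point ROC AUC of a binary positivity rule
#'
#' The ROC of a binary rule has a single interior operating point; the
#' trapezoidal area under the curve through (0, 0), (1 - specificity,
#' sensitivity) and (1, 1) equals `(sensitivity + specificity) / 2`, which
#' is also the Mann-Whitney statistic of the 0/1 score with ties counted as
#' one half.
#'
#' @inheritParams confusion
#' @return the AUC, a number in `[0, 1]`.
#' @examples
#' binary_roc_auc(c(TRUE, FALSE, FALSE), c("HCC", "HCC", "BENIGN"))
#' @export
binary_roc_auc <- function(positives, truth) {
  ct <- confusion(positives, truth)
  m <- ct$tp + ct$fn
  n <- ct$fp + ct$tn
  if (m == 0 || n == 0) {
    stop("degenerate truth vector: need at least one HCC and one non-HCC observation")
  }
  tpr <- ct$tp / m
  fpr <- ct$fp / n
  # trapezoids: (0,0)-(fpr,tpr) and (fpr,tpr)-(1,1)
  fpr * tpr / 2 + (1 - fpr) * (tpr + 1) / 2
}

#' Paired comparison of two binary rules on the same cohort
#'
#' Compares two correlated positivity rules: the difference in two-point
#' ROC AUCs is tested with the DeLong placement-value covariance estimator
#' (ties, which are massive for 0/1 scores, are handled by the placement
#' values), and the discordant pairs within one truth class are tested with
#' the exact McNemar test -- within the HCC class when sensitivities are
#' compared, within the non-HCC class for specificities.
#'
#' @param pos1,pos2 logical positivity vectors for the two rules.
#' @param truth shared diagnosis vector.
#' @param compare `"sensitivity"` (default) or `"specificity"`: which truth
#'   class the McNemar test is computed on.
#' @return object of class `paired_result`: list with the two AUCs,
#'   `delta_auc`, `z`, `p_delong`, the discordant counts `b` (rule-1
#'   positive only) and `c` (rule-2 positive only), and `p_mcnemar`.
#' @examples
#' truth <- c("HCC", "HCC", "HCC", "BENIGN", "BENIGN")
#' delong_paired(c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'               c(TRUE, TRUE, TRUE, FALSE, FALSE), truth)
#' @export
delong_paired <- function(pos1, pos2, truth,
                          compare = c("sensitivity", "specificity")) {
  compare <- match.arg(compare)
  if (length(pos1) != length(truth) || length(pos2) != length(truth)) {
    stop("pos1, pos2 and truth must have the same length")
  }
  pos_truth <- truth == "HCC"
  m <- sum(pos_truth)
  n <- sum(!pos_truth)
  if (m == 0 || n == 0) {
    stop("degenerate truth vector: need at least one HCC and one non-HCC observation")
  }
  scores <- cbind(as.numeric(pos1), as.numeric(pos2))
  placements <- function(score) {
    x <- score[pos_truth]
    y <- score[!pos_truth]
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  p1 <- placements(scores[, 1])
  p2 <- placements(scores[, 2])
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- p1$auc - p2$auc
  if (var_delta <= .Machine$double.eps) {
    z <- 0
    p_delong <- 1
    if (abs(delta) > 0) {
      z <- sign(delta) * Inf
      p_delong <- .Machine$double.xmin
    }
  } else {
    z <- delta / sqrt(var_delta)
    p_delong <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)
  }
  subset <- if (compare == "sensitivity") pos_truth else !pos_truth
  b <- sum(pos1 & !pos2 & subset)
  c_ <- sum(!pos1 & pos2 & subset)
  structure(
    list(auc1 = p1$auc, auc2 = p2$auc, delta_auc = delta,
         z = z, p_delong = p_delong,
         compare = compare, b = b, c = c_,
         p_mcnemar = mcnemar_exact(b, c_)),
    class = "paired_result"
  )
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("Paired comparison (%s): AUC %.3f vs %.3f, delta %.3f, z = %.2f, p(DeLong) = %s\n",
              x$compare, x$auc1, x$auc2, x$delta_auc, x$z, format_pvalue(x$p_delong)))
  cat(sprintf("  discordant pairs b = %d, c = %d, p(McNemar exact) = %s\n",
              x$b, x$c, format_pvalue(x$p_mcnemar)))
  invisible(x)
}
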