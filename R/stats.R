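# Diagnostic-accuracy and comparison statistics.

#' Build a 2x2 confusion table
#'
#' Cross-tabulates predicted against true labels for a chosen positive class.
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive The label counted as positive (e.g. `"mPCN"`,
#'   `"mucinous"`).
#' @return An object of class `confusion_table` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(pred, truth, positive) {
  if (length(pred) != length(truth)) abort("pred and truth lengths differ")
  if (length(pred) == 0) abort("empty label vectors")
  p <- pred == positive
  t <- truth == positive
  structure(
    list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t)),
    class = "confusion_table"
  )
}

# Percent to one decimal, rounding half away from zero (clinical convention).
.percent1 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 10

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Accuracy metrics of a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy, as proportions and as percentages rounded to one decimal (half
#' away from zero). A metric whose denominator is zero is reported missing.
#'
#' @param ct A [confusion()] table.
#' @return A tibble with columns `metric`, `proportion`, `percent`.
#' @export
confusion_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  props <- c(
    sensitivity = .safe_ratio(ct$tp, ct$tp + ct$fn),
    specificity = .safe_ratio(ct$tn, ct$tn + ct$fp),
    ppv = .safe_ratio(ct$tp, ct$tp + ct$fp),
    npv = .safe_ratio(ct$tn, ct$tn + ct$fn),
    accuracy = .safe_ratio(ct$tp + ct$tn, ct$tp + ct$fp + ct$fn + ct$tn)
  )
  props <- unname(props)
  tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy"),
    proportion = props,
    percent = ifelse(is.na(props), NA_real_, .percent1(props))
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  m <- confusion_metrics(x)
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %s\n", m$metric[i],
                ifelse(is.na(m$percent[i]), "undefined",
                       sprintf("%.1f%%", m$percent[i]))))
  }
  invisible(x)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing, over all tables with the observed margins, the
#' hypergeometric probabilities no larger than that of the observed table.
#'
#' @param table A 2x2 matrix of non-negative integer counts, or a
#'   [confusion()] table.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (inherits(table, "confusion_table")) {
    table <- matrix(c(table$tp, table$fn, table$fp, table$tn), 2, 2)
  }
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table %% 1 != 0)) {
    abort("counts must be non-negative integers")
  }
  if (sum(table) == 0) abort("empty table")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Exact Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum test. For small samples (combined n at or below
#' `exact_limit`) the exact permutation distribution of the rank sum is
#' computed by dynamic programming over midranks, so ties are handled exactly;
#' larger samples use the normal approximation with tie and continuity
#' correction. The method actually used is recorded as an attribute.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Largest combined sample size for exact enumeration
#'   (default 25).
#' @return The two-sided p-value, with attributes `method`
#'   (`"exact"`/`"normal_approx"`) and `statistic` (the Mann-Whitney U for
#'   `x`).
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 25) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  m <- length(x)
  n_all <- m + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  u <- w - m * (m + 1) / 2
  if (n_all <= exact_limit) {
    s <- as.integer(round(2 * r))  # doubled midranks are integers
    total <- sum(s)
    # dp[k+1, v+1] = number of size-k subsets with doubled-rank sum v
    dp <- matrix(0, nrow = m + 1, ncol = total + 1)
    dp[1, 1] <- 1
    for (si in s) {
      kmax <- min(m, nrow(dp) - 1)
      for (k in kmax:1) {
        idx <- (si + 1):(total + 1)
        dp[k + 1, idx] <- dp[k + 1, idx] + dp[k, idx - si]
      }
    }
    counts <- dp[m + 1, ]
    denom <- choose(n_all, m)
    w2 <- round(2 * w)
    lower <- sum(counts[seq_len(w2 + 1)]) / denom
    upper <- sum(counts[(w2 + 1):(total + 1)]) / denom
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    n2 <- length(y)
    mu <- m * n2 / 2
    tie_tab <- table(r)
    n <- n_all
    sigma2 <- m * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(p, method = method, statistic = u)
}

#' ROC analysis with Youden-optimal threshold
#'
#' Sweeps every threshold that can matter — the midpoints between consecutive
#' distinct sorted scores, plus sentinels below and above the data — calling
#' a case positive when its score is at or above the threshold. The optimal
#' threshold maximizes the Youden index (sensitivity + specificity - 1); ties
#' go to the lowest threshold (favoring sensitivity, the screening
#' convention). AUC is the trapezoidal area under the
#' sensitivity/1-specificity curve.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical (or 0/1) vector; `TRUE` marks the positive class.
#'   Both classes must be present.
#' @param criterion Threshold selection criterion; only `"youden"`.
#' @return An object of class `roc_result`: `points` (tibble of threshold,
#'   sensitivity, specificity), `auc`, `optimal_threshold`, `criterion`.
#' @export
roc_threshold <- function(scores, labels, criterion = "youden") {
  criterion <- match.arg(criterion, "youden")
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels lengths differ")
  if (any(is.na(scores)) || any(is.na(labels))) abort("missing scores/labels")
  if (!any(labels) || all(labels)) abort("both classes must be present")
  sorted <- sort(unique(scores))
  thr <- c(-Inf, if (length(sorted) > 1) (sorted[-1] + sorted[-length(sorted)]) / 2,
           Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))[1]  # thresholds ascend, so first = lowest
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(
    list(points = tibble::tibble(threshold = thr, sensitivity = sens,
                                 specificity = spec),
         auc = abs(auc),
         optimal_threshold = thr[best],
         criterion = criterion),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds; AUC %.3f; optimal threshold %.4g (%s)\n",
              nrow(x$points), x$auc, x$optimal_threshold, x$criterion))
  invisible(x)
}
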