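#' Empirical ROC analysis with DeLong confidence interval
#'
#' Builds the empirical ROC curve over all observed thresholds, computes the
#' area under it (equivalently the Mann-Whitney statistic, via midranks so
#' ties contribute 1/2), a DeLong 95\% confidence interval from the
#' positive/negative placement variances, and the optimal threshold by the
#' Youden index J = sensitivity + specificity - 1 (ties broken towards
#' higher specificity). The reading direction is chosen automatically so
#' that AUC >= 0.5 unless fixed by the caller.
#'
#' @param values Numeric criterion values.
#' @param labels Logical (or 0/1) class labels; both classes must be
#'   present.
#' @param direction `"auto"` (default), `"higher"` (larger values indicate a
#'   positive) or `"lower"`.
#' @param conf_level Confidence level for the DeLong interval.
#' @return An object of class `roc_result`: list with `auc`, `auc_ci`,
#'   `direction`, `best_threshold`, `sensitivity`, `specificity`, `youden`
#'   and `curve` (data.frame of threshold, sensitivity, specificity). With
#'   direction `"higher"` a case is called positive when its value is `>=`
#'   the threshold; with `"lower"`, when it is `<=` the threshold.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(50, 1), rnorm(50, 0))
#' roc_analysis(v, rep(c(TRUE, FALSE), each = 50))$auc
#' @export
roc_analysis <- function(values, labels, direction = c("auto", "higher",
                                                       "lower"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  n1 <- as.numeric(sum(labels))
  n0 <- as.numeric(sum(!labels))
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }

  auc_for <- function(score) {
    r <- rank(score)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (direction == "auto") {
    direction <- if (auc_for(values) >= 0.5) "higher" else "lower"
  }
  score <- if (direction == "higher") values else -values

  r <- rank(score)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements: V10_i = fraction of negatives below positive i
  # (ties count 1/2), V01_j likewise for negatives among positives
  v10 <- (r[labels] - rank(score[labels])) / n0
  v01 <- 1 - (r[!labels] - rank(score[!labels])) / n1
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- clamp(auc + c(-1, 1) * z * se, 0, 1)

  # empirical curve: positive call at score >= s for each distinct s
  os <- order(score, decreasing = TRUE)
  ss <- score[os]
  ll <- labels[os]
  # cumulative counts at the final occurrence of each distinct score
  ctp <- cumsum(ll)
  cfp <- cumsum(!ll)
  keep <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  sens <- c(0, ctp[keep] / n1)
  spec <- c(1, 1 - cfp[keep] / n0)
  thr_score <- c(Inf, ss[keep])
  thr <- if (direction == "higher") thr_score else -thr_score

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]

  structure(
    list(auc = auc, auc_ci = ci, auc_se = se, direction = direction,
         best_threshold = thr[best], sensitivity = sens[best],
         specificity = spec[best], youden = j[best],
         n_positive = n1, n_negative = n0,
         curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  rule <- if (x$direction == "higher") ">=" else "<="
  cat(sprintf(
    paste0("<roc_result> AUC %.3f (95%% CI %.3f-%.3f); best threshold ",
           "value %s %.4g: sens %.2f, spec %.2f\n"),
    x$auc, x$auc_ci[1], x$auc_ci[2], rule, x$best_threshold,
    x$sensitivity, x$specificity
  ))
  invisible(x)
}
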