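#' Spearman rank correlation with a two-tailed p-value
#'
#' Computes `r_s` as the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-tailed p-value uses the exact permutation distribution for
#' `n <= 8` and the t approximation
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))` above that; `|r_s| = 1` gives
#' `p = 0` under the t branch.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param metric_name label carried into the result.
#' @return A list of class `correlation_result`: `metric_name`, `r_s`,
#'   `p_value`, `n`.
#' @examples
#' spearman_with_p(1:5, c(1, 2, 3, 5, 4))$r_s # 0.9
#' @export
spearman_with_p <- function(x, y, metric_name = "metric") {
  if (length(x) != length(y)) stopf("spearman_with_p: unequal lengths")
  n <- length(x)
  if (n < 3L) stopf("spearman_with_p: need n >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stopf("undefined correlation: constant input vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r_s <- stats::cor(rx, ry)
  p <- if (n <= 8L) {
    perms <- all_permutations(n)
    null_r <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    mean(abs(null_r) >= abs(r_s) - 1e-12)
  } else if (abs(r_s) >= 1) {
    0
  } else {
    tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(metric_name = metric_name, r_s = r_s, p_value = p, n = n),
    class = "correlation_result"
  )
}

all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE], n,
      sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE]
    )
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Pass/fail labels from measured gamma passing rates
#'
#' @param gpr_percent numeric GPR values (percent).
#' @param pass_threshold passing threshold (percent, default 95); a beam
#'   passes when `gpr_percent >= pass_threshold`.
#' @return Logical vector; `TRUE` = pass (the positive class).
#' @export
classify_labels <- function(gpr_percent, pass_threshold = 95) {
  if (pass_threshold <= 0 || pass_threshold >= 100) {
    stopf("pass_threshold must lie in (0, 100)")
  }
  gpr_percent >= pass_threshold
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return Named vector `sensitivity = tp / (tp + fn)`,
#'   `specificity = tn / (tn + fp)`.
#' @export
sensitivity_specificity <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) stopf("undefined rate: empty margin")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' ROC analysis of a complexity metric against pass/fail labels
#'
#' Orients the score so that larger oriented values predict the positive
#' class (orientation chosen so AUC >= 0.5), computes the AUC as the
#' Mann-Whitney rank statistic (half credit for ties), and picks the
#' operating threshold maximizing Youden's `J = sensitivity + specificity -
#' 1` (ties resolved toward the positive-class median score). The chosen
#' threshold is reported in the original metric units; a beam is predicted
#' positive when `orientation * score >= orientation * threshold`.
#'
#' @param scores numeric metric values.
#' @param labels logical labels (`TRUE` = positive class).
#' @param metric_name label carried into the result.
#' @return A list of class `roc_result`: `metric_name`, `auc`, `thresholds`,
#'   `tpr`, `fpr`, `chosen_threshold`, `sensitivity`, `specificity`,
#'   `orientation`.
#' @examples
#' roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))$auc # 0.75
#' @export
roc_analysis <- function(scores, labels, metric_name = "metric") {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stopf("degenerate ROC: single-class labels")

  auc_oriented <- function(s) {
    r <- rank(s, ties.method = "average")
    (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  a <- auc_oriented(scores)
  orientation <- if (a >= 0.5) 1 else -1
  auc <- if (orientation == 1) a else 1 - a

  s <- orientation * scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & !labels) / n_neg, numeric(1))
  j <- tpr - fpr
  best <- which(abs(j - max(j)) < 1e-12)
  if (length(best) > 1L) {
    pos_med <- median(s[labels])
    best <- best[which.min(abs(thr[best] - pos_med))]
  }
  chosen <- thr[best]
  tp <- sum(s >= chosen & labels)
  fp <- sum(s >= chosen & !labels)
  ss <- sensitivity_specificity(tp, fp, n_neg - fp, n_pos - tp)
  structure(
    list(
      metric_name = metric_name, auc = auc,
      thresholds = orientation * thr, tpr = tpr, fpr = fpr,
      chosen_threshold = orientation * chosen,
      sensitivity = unname(ss["sensitivity"]),
      specificity = unname(ss["specificity"]),
      orientation = orientation
    ),
    class = "roc_result"
  )
}

#' Correlate every complexity metric with measured GPR
#'
#' @param merged data.frame holding the 27 metric columns plus
#'   `gpr_percent` (see [join_metrics_qa()]).
#' @param metrics character vector of metric columns (default all 27).
#' @return data.frame `metric, r_s, p, n`, ordered as `metrics`.
#' @export
correlate_metrics <- function(merged, metrics = metric_names()) {
  rows <- lapply(metrics, function(m) {
    res <- tryCatch(
      spearman_with_p(merged[[m]], merged$gpr_percent, m),
      error = function(e) list(metric_name = m, r_s = NA_real_, p_value = NA_real_, n = nrow(merged))
    )
    data.frame(
      metric = m, r_s = res$r_s, p = res$p_value, n = res$n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-site descriptive statistics and metric AUCs
#'
#' One row per treatment site plus an `"All"` row: beam counts above/below
#' the pass threshold, mean and SD of GPR (overall and within each class),
#' the mean of each selected metric, and each metric's single-site ROC AUC
#' (NA when a site has a single class).
#'
#' @param merged data.frame with metric columns, `site` and `gpr_percent`.
#' @param metrics metric columns to summarize.
#' @param pass_threshold GPR pass threshold (percent).
#' @return data.frame, one row per site plus `"All"`. Sites emptied by
#'   filtering are dropped with a warning.
#' @export
descriptive_by_site <- function(merged, metrics = c("LAAM", "AAJA", "M", "LT"),
                                pass_threshold = 95) {
  site <- ifelse(is.na(merged$site) | merged$site == "", "unknown", merged$site)
  groups <- c(list(All = seq_len(nrow(merged))), split(seq_len(nrow(merged)), site))
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0L) {
      warning(sprintf("site %s has no beams after filtering; row omitted", g))
      next
    }
    gpr <- merged$gpr_percent[idx]
    pass <- classify_labels(gpr, pass_threshold)
    row <- data.frame(
      site = g, n_beams = length(idx), n_pass = sum(pass), n_fail = sum(!pass),
      gpr_mean = mean(gpr), gpr_sd = sd(gpr),
      gpr_mean_pass = if (any(pass)) mean(gpr[pass]) else NA_real_,
      gpr_mean_fail = if (any(!pass)) mean(gpr[!pass]) else NA_real_,
      stringsAsFactors = FALSE
    )
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(merged[[m]][idx])
      row[[paste0(m, "_auc")]] <- if (length(unique(pass)) == 2L) {
        roc_analysis(merged[[m]][idx], pass, m)$auc
      } else {
        NA_real_
      }
    }
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
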