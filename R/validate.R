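#' Apply a locked diffpair rule to new samples
#'
#' Predicts cancer/control per sample from the rule's cutoff and direction
#' alone; the operation takes no labels, so no re-optimization on validation
#' data is possible. If the diffpair matrix stores the pair in the opposite
#' orientation, the rule is applied to the negated column, which is the
#' identical classifier.
#'
#' @param rule a \code{\link{diffpair_rule}}.
#' @param dp a \code{diffpair_matrix} containing the rule's pair.
#' @return named character vector of \code{"cancer"}/\code{"control"}
#'   predictions, one per sample.
#' @export
apply_rule <- function(rule, dp) {
  stopifnot(inherits(rule, "diffpair_rule"), inherits(dp, "diffpair_matrix"))
  hit <- find_pair(dp, rule$mirna_a, rule$mirna_b)
  values <- hit$sign * dp$delta_ct[, hit$col]
  stats::setNames(classify_values(rule, values), dp$sample_ids)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from inversion of the binomial tail probabilities,
#' computed via beta-distribution quantiles. The lower bound is 0 exactly
#' when k = 0 and the upper bound 1 exactly when k = n.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric vector \code{c(lo, hi)}.
#' @export
#' @examples
#' clopper_pearson_ci(55, 55) # lower bound 0.9351...
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop2("need integer 0 <= k <= n with n >= 1")
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Conservative display rounding for a confidence interval
#'
#' Rounds the lower bound down and the upper bound up, so the printed
#' interval always contains the computed one. This is the convention behind
#' published interval displays such as "0.93-1.0" for an exact lower bound
#' of 0.9351: rounding the lower bound to nearest (0.94) would overstate the
#' evidence.
#'
#' @param ci numeric \code{c(lo, hi)}.
#' @param digits decimal places (default 2).
#' @return \code{c(lo, hi)} rounded outward.
#' @export
round_ci_outward <- function(ci, digits = 2) {
  scale <- 10^digits
  c(lo = floor(ci[[1]] * scale) / scale, hi = ceiling(ci[[2]] * scale) / scale)
}

#' Confusion-matrix diagnostic metrics with exact CIs
#'
#' Cross-tabulates predictions against truth and reports sensitivity,
#' specificity, PPV and NPV with exact binomial confidence intervals for
#' sensitivity and specificity. A ratio with a zero denominator (e.g. NPV
#' when no sample is predicted negative) is reported as \code{NA} with a
#' warning, never coerced to 0 or 1.
#'
#' @param pred,truth cancer/control label vectors of equal length; truth
#'   must contain both classes.
#' @param level confidence level for the exact intervals.
#' @return list with counts (\code{tp}, \code{fp}, \code{tn}, \code{fn}),
#'   proportions (\code{sens}, \code{spec}, \code{ppv}, \code{npv}), and
#'   intervals (\code{sens_ci}, \code{spec_ci}).
#' @export
confusion_metrics <- function(pred, truth, level = 0.95) {
  if (length(pred) != length(truth))
    stop2("pred and truth must have equal length")
  p <- as_cancer(pred); t <- as_cancer(truth)
  if (!any(t) || all(t)) stop2("truth must contain both classes")
  tp <- sum(p & t); fp <- sum(p & !t)
  tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den, what) {
    if (den > 0L) return(num / den)
    warning(what, " undefined (zero denominator); reported as NA",
            call. = FALSE)
    NA_real_
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       ppv = ratio(tp, tp + fp, "PPV"), npv = ratio(tn, tn + fn, "NPV"),
       sens_ci = clopper_pearson_ci(tp, tp + fn, level),
       spec_ci = clopper_pearson_ci(tn, tn + fp, level))
}

#' Validate training-locked rules on the independent test cohort
#'
#' Applies each rule, with its training cutoff unchanged, to the test-split
#' samples and reports the resulting confusion metrics, exact confidence
#' intervals, and the Welch two-sided p-value comparing the pair's test-set
#' delta-Ct between cancers and controls. Rules reaching both gates
#' (boundary inclusive: "at least" \code{sens_min}/\code{spec_min}) are
#' flagged \code{passed_gate}. The input rules are returned verbatim in the
#' output columns; nothing is re-fit.
#'
#' @param rules list of \code{\link{diffpair_rule}} objects (e.g. from
#'   \code{\link{rules_from_screen}}).
#' @param dp_test \code{diffpair_matrix} covering the test samples (extra
#'   samples are ignored via \code{meta}).
#' @param meta cohort metadata; only \code{split == "test"} samples are used.
#' @param sens_min,spec_min validation gate (default 0.75 each).
#' @param level confidence level for exact intervals.
#' @return data.frame, one row per rule, ranked by descending sens + spec
#'   then ascending p: \code{mirna_a}, \code{mirna_b}, \code{pair},
#'   \code{cutoff}, \code{direction}, \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}, \code{sens}, \code{spec}, \code{ppv}, \code{npv},
#'   \code{sens_ci_lo/hi}, \code{spec_ci_lo/hi}, \code{p_value},
#'   \code{passed_gate}.
#' @export
validate_candidates <- function(rules, dp_test, meta,
                                sens_min = 0.75, spec_min = 0.75,
                                level = 0.95) {
  if (!length(rules)) stop2("empty rule list")
  stopifnot(inherits(dp_test, "diffpair_matrix"))
  meta <- validate_cohort_metadata(meta)
  mm <- meta_for_samples(meta, dp_test$sample_ids)
  test <- mm$split == "test"
  if (!any(test)) stop2("no test-split samples present")
  truth <- as_cancer(mm$group)[test]
  if (!any(truth) || all(truth)) stop2("test split must contain both classes")

  rows <- lapply(rules, function(rule) {
    stopifnot(inherits(rule, "diffpair_rule"))
    hit <- find_pair(dp_test, rule$mirna_a, rule$mirna_b)
    v <- (hit$sign * dp_test$delta_ct[, hit$col])[test]
    pred <- classify_values(rule, v) == "cancer"
    cm <- confusion_metrics(pred, truth, level)
    wt <- welch_t_test(v[truth], v[!truth])
    data.frame(
      mirna_a = rule$mirna_a, mirna_b = rule$mirna_b,
      pair = pair_label(rule$mirna_a, rule$mirna_b),
      cutoff = rule$cutoff, direction = rule$direction,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      sens = cm$sens, spec = cm$spec, ppv = cm$ppv, npv = cm$npv,
      sens_ci_lo = cm$sens_ci[["lo"]], sens_ci_hi = cm$sens_ci[["hi"]],
      spec_ci_lo = cm$spec_ci[["lo"]], spec_ci_hi = cm$spec_ci[["hi"]],
      p_value = wt$p_value,
      passed_gate = cm$sens >= sens_min & cm$spec >= spec_min,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-(res$sens + res$spec), res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
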