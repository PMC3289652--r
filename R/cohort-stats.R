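#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact independence test with both margins fixed. The two-sided p-value is
#' the sum of hypergeometric point probabilities, over all tables with the
#' observed margins, that do not exceed the observed table's own probability
#' (the "sum of small p" definition, which is the one that matches standard
#' statistical software; doubling a single tail does not). Point
#' probabilities are accumulated on the log scale via log-factorials for
#' numerical safety; a small relative tolerance guards the \code{<=}
#' comparison against floating-point noise. A table with an all-zero row or
#' column is degenerate and returns p = 1 by convention (with a message).
#'
#' @param tab 2x2 numeric matrix of non-negative integer counts, rows =
#'   cohort group, columns = attribute present/absent.
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(9, 11, 24, 6), 2, byrow = TRUE))
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(is.na(tab)) ||
      any(tab < 0) || any(tab != round(tab)))
    stop2("need a 2x2 table of non-negative integer counts")
  if (sum(tab) == 0) stop2("table must contain at least one count")
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    message("degenerate margin; p = 1 by convention")
    return(1)
  }
  # hypergeometric support for the top-left cell
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(support) + lfactorial(r1 - support) +
       lfactorial(c1 - support) + lfactorial(r2 - c1 + support))
  lp_obs <- logp[support == tab[1L, 1L]]
  p <- sum(exp(logp[logp <= lp_obs + log(1 + 1e-7)]))
  min(p, 1)
}

#' Reconstruct a count from a published percentage
#'
#' Published demographic tables often report group percentages rather than
#' counts; this inverts the rounding (half away from zero) and warns when the
#' back-computed percentage differs from the printed one by more than half a
#' point, i.e. when no count reproduces the printed value exactly.
#'
#' @param pct percentage in [0, 100].
#' @param n group size (>= 1).
#' @return list with \code{count} and \code{pct_back} (the percentage the
#'   count actually implies).
#' @export
#' @examples
#' counts_from_percent(45, 20)  # 9 smokers among 20 controls
counts_from_percent <- function(pct, n) {
  if (is.na(pct) || pct < 0 || pct > 100 || n < 1)
    stop2("need 0 <= pct <= 100 and n >= 1")
  count <- round_half_up(pct * n / 100)
  pct_back <- 100 * count / n
  if (abs(pct_back - pct) > 0.5)
    warning(sprintf("percentage %g%% of n=%d is not attainable; using %d (%.1f%%)",
                    pct, n, count, pct_back), call. = FALSE)
  list(count = count, pct_back = pct_back)
}

#' Test association between cancer status and a binary cohort attribute
#'
#' Builds the 2x2 table of group (cancer/control) against a logical metadata
#' column within one cohort split and runs the two-sided Fisher exact test.
#'
#' @param meta cohort metadata data.frame.
#' @param attribute name of a logical column (e.g. \code{"smoker"});
#'   missing values are dropped with a message.
#' @param split restrict to \code{"train"} or \code{"test"} samples, or
#'   \code{NULL} for all.
#' @return list with the 2x2 \code{table} (rows control/cancer, columns
#'   attribute FALSE/TRUE) and \code{p_value}.
#' @export
cohort_association_test <- function(meta, attribute, split = NULL) {
  meta <- validate_cohort_metadata(meta)
  if (!attribute %in% names(meta)) stop2("no metadata column '", attribute, "'")
  if (!is.null(split)) meta <- meta[meta$split == split, , drop = FALSE]
  x <- meta[[attribute]]
  keep <- !is.na(x)
  if (!all(keep)) message(sum(!keep), " sample(s) with missing '", attribute,
                          "' dropped")
  tab <- table(factor(meta$group[keep], levels = c("control", "cancer")),
               factor(x[keep], levels = c(FALSE, TRUE)))
  tab <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(group = c("control", "cancer"),
                                stats::setNames(c("no", "yes"), NULL)))
  list(table = tab, p_value = fisher_exact_two_sided(tab))
}
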