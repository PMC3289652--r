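# Accept labels as "cancer"/"control" strings, a factor, or a logical
# is-cancer vector; return logical.
as_cancer <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("cancer", "control")))
    stop2("labels must be 'cancer'/'control' (or logical is-cancer)")
  l == "cancer"
}

#' Welch unequal-variance t-test
#'
#' Two-sample t-test without the equal-variance assumption; the degrees of
#' freedom follow the Welch-Satterthwaite approximation and are left
#' fractional. The sign of t follows \code{mean(x) - mean(y)}; the p-value is
#' two-sided. When both groups are constant and equal the statistic is
#' undefined and p = 1 is returned by convention (with a message).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with \code{t_stat}, \code{df}, \code{p_value}.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop2("each group needs at least two observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mx == my) {
      message("both groups constant and equal; p = 1 by convention")
      return(list(t_stat = 0, df = nx + ny - 2, p_value = 1))
    }
    return(list(t_stat = sign(mx - my) * Inf, df = nx + ny - 2, p_value = 0))
  }
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

# Vectorised Welch over the columns of cancer/control value matrices.
welch_t_cols <- function(xc, xo) {
  n1 <- nrow(xc); n0 <- nrow(xo)
  m1 <- colMeans(xc); m0 <- colMeans(xo)
  v1 <- colSums((xc - rep(m1, each = n1))^2) / (n1 - 1)
  v0 <- colSums((xo - rep(m0, each = n0))^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2),
                   ifelse(m1 == m0, 0, sign(m1 - m0) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               n1 + n0 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(m1 == m0, 1, 0))
  list(t_stat = t_stat, df = df, p_value = p)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve via the Mann-Whitney identity: the probability
#' that a random cancer value exceeds a random control value, counting ties
#' as one half. The orientation making AUC >= 0.5 is chosen and reported, so
#' a pair discriminating in either direction scores above chance.
#'
#' @param values numeric scores (e.g. one diffpair column).
#' @param labels cancer/control labels (see \code{\link{welch_t_test}}).
#' @return list with \code{auc} (>= 0.5) and \code{direction}
#'   (\code{"cancer_above"} or \code{"cancer_below"}).
#' @export
roc_auc <- function(values, labels) {
  is_cancer <- as_cancer(labels)
  n1 <- sum(is_cancer); n0 <- sum(!is_cancer)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[is_cancer]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc >= 0.5) list(auc = auc, direction = "cancer_above")
  else list(auc = 1 - auc, direction = "cancer_below")
}

#' ROC curve points
#'
#' All (false positive rate, true positive rate) operating points of the
#' cancer-above rule family over the midpoint threshold grid, for plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(values, labels) {
  is_cancer <- as_cancer(labels)
  thr <- threshold_grid(values)
  sc <- sort(values[is_cancer]); so <- sort(values[!is_cancer])
  tpr <- (length(sc) - findInterval(thr, sc)) / length(sc)
  fpr <- (length(so) - findInterval(thr, so)) / length(so)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

# Midpoints between adjacent distinct sorted values, plus -Inf/+Inf
# sentinels; guarantees no observation ever sits on a finite threshold.
threshold_grid <- function(values) {
  v <- sort(unique(values))
  if (length(v) > 1L) c(-Inf, (v[-length(v)] + v[-1L]) / 2, Inf)
  else c(-Inf, Inf)
}

#' Select the cutoff maximizing sensitivity + specificity
#'
#' Exhaustive search over the midpoint threshold grid and both rule
#' directions for the Youden-style maximizer of sensitivity plus specificity
#' on the supplied (training) data. A sample exactly on the cutoff is
#' classified control; with midpoint cutoffs no training sample ever sits on
#' the boundary. Ties are broken by (1) larger min(sensitivity,
#' specificity), (2) smaller |cutoff|, (3) direction cancer-above, then grid
#' order, making the selection deterministic.
#'
#' @inheritParams roc_auc
#' @return list with \code{cutoff}, \code{direction}, \code{sens},
#'   \code{spec} (training-set values at the chosen rule).
#' @export
select_cutoff <- function(values, labels) {
  is_cancer <- as_cancer(labels)
  n1 <- sum(is_cancer); n0 <- sum(!is_cancer)
  if (n1 == 0L || n0 == 0L) stop2("both classes must be present")
  thr <- threshold_grid(values)
  sc <- sort(values[is_cancer]); so <- sort(values[!is_cancer])
  # counts <= t; thresholds never coincide with finite data values
  c_le <- findInterval(thr, sc); o_le <- findInterval(thr, so)
  cand <- data.frame(
    cutoff = c(thr, thr),
    direction = rep(c("cancer_above", "cancer_below"), each = length(thr)),
    sens = c((n1 - c_le) / n1, c_le / n1),
    spec = c(o_le / n0, (n0 - o_le) / n0),
    stringsAsFactors = FALSE)
  j <- cand$sens + cand$spec
  best <- order(-j, -pmin(cand$sens, cand$spec), abs(cand$cutoff),
                cand$direction != "cancer_above")[1L]
  as.list(cand[best, , drop = FALSE])
}

#' Construct a diffpair classification rule
#'
#' The unit transferred from training to validation: one miRNA pair, one
#' delta-Ct cutoff, one direction. A sample is called cancer when its
#' diffpair value lies strictly beyond the cutoff in the rule's direction;
#' a value exactly at the cutoff is called control. Flipping the pair
#' orientation while negating the cutoff and toggling the direction yields
#' the identical classifier.
#'
#' @param mirna_a,mirna_b the pair members, in the rule's orientation
#'   (diffpair value = Ct(a) - Ct(b)).
#' @param cutoff delta-Ct threshold (cycles).
#' @param direction \code{"cancer_above"} or \code{"cancer_below"}.
#' @return an object of class \code{diffpair_rule}.
#' @export
diffpair_rule <- function(mirna_a, mirna_b, cutoff, direction) {
  direction <- match.arg(direction, c("cancer_above", "cancer_below"))
  structure(list(mirna_a = mirna_a, mirna_b = mirna_b,
                 cutoff = cutoff, direction = direction),
            class = "diffpair_rule")
}

#' @export
print.diffpair_rule <- function(x, ...) {
  cat(sprintf("diffpair rule: Ct(%s) - Ct(%s) %s %g -> cancer\n",
              x$mirna_a, x$mirna_b,
              if (x$direction == "cancer_above") ">" else "<", x$cutoff))
  invisible(x)
}

# Classify a numeric vector of diffpair values under a rule.
classify_values <- function(rule, values) {
  pos <- if (rule$direction == "cancer_above") values > rule$cutoff
         else values < rule$cutoff
  ifelse(pos, "cancer", "control")
}

#' Screen every diffpair on the training cohort
#'
#' For each unordered miRNA pair, computes on the training split: the Welch
#' t statistic and two-sided p-value comparing cancer vs control delta-Ct,
#' the rank-based ROC AUC, the cutoff maximizing sensitivity + specificity,
#' and the training (resubstitution) sensitivity, specificity, PPV and NPV
#' of the resulting rule. Pairs with sensitivity and specificity both at or
#' above the gate become candidates for independent validation. Gating uses
#' sensitivity/specificity only; p-values are reported raw, uncorrected, and
#' never consulted by the gate.
#'
#' @param dp a \code{diffpair_matrix}.
#' @param meta cohort metadata (see \code{\link{read_cohort_metadata}});
#'   only \code{split == "train"} samples are used.
#' @param sens_min,spec_min candidate gate (proportions, default 0.80 each).
#' @return data.frame of class \code{screen_result}, one row per pair,
#'   ordered by descending sens + spec then ascending p: columns
#'   \code{mirna_a}, \code{mirna_b}, \code{pair}, \code{cutoff},
#'   \code{direction}, \code{t_stat}, \code{df}, \code{p_value}, \code{auc},
#'   \code{sens}, \code{spec}, \code{ppv}, \code{npv}, \code{is_candidate}.
#' @export
screen_all <- function(dp, meta, sens_min = 0.80, spec_min = 0.80) {
  stopifnot(inherits(dp, "diffpair_matrix"))
  meta <- validate_cohort_metadata(meta)
  mm <- meta_for_samples(meta, dp$sample_ids)
  train <- mm$split == "train"
  is_cancer <- as_cancer(mm$group)[train]
  x <- dp$delta_ct[train, , drop = FALSE]
  n1 <- sum(is_cancer); n0 <- sum(!is_cancer)
  if (n1 < 2L || n0 < 2L)
    stop2("training split needs >= 2 cancers and >= 2 controls")

  wt <- welch_t_cols(x[is_cancer, , drop = FALSE], x[!is_cancer, , drop = FALSE])

  np <- ncol(x)
  auc <- numeric(np); cutoff <- numeric(np); direction <- character(np)
  sens <- numeric(np); spec <- numeric(np); ppv <- numeric(np); npv <- numeric(np)
  for (jp in seq_len(np)) {
    v <- x[, jp]
    a <- roc_auc(v, is_cancer)
    auc[jp] <- a$auc
    cs <- select_cutoff(v, is_cancer)
    cutoff[jp] <- cs$cutoff; direction[jp] <- cs$direction
    sens[jp] <- cs$sens; spec[jp] <- cs$spec
    pos <- if (cs$direction == "cancer_above") v > cs$cutoff else v < cs$cutoff
    tp <- sum(pos & is_cancer); fp <- sum(pos & !is_cancer)
    tn <- sum(!pos & !is_cancer); fn <- sum(!pos & is_cancer)
    ppv[jp] <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    npv[jp] <- if (tn + fn > 0L) tn / (tn + fn) else NA_real_
  }

  res <- data.frame(
    mirna_a = dp$pairs$mirna_a, mirna_b = dp$pairs$mirna_b,
    pair = colnames(x),
    cutoff = cutoff, direction = direction,
    t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value,
    auc = auc, sens = sens, spec = spec, ppv = ppv, npv = npv,
    is_candidate = sens >= sens_min & spec >= spec_min,
    stringsAsFactors = FALSE)
  res <- res[order(-(res$sens + res$spec), res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Unique miRNAs appearing in a set of screen records
#'
#' @param records data.frame with \code{mirna_a}/\code{mirna_b} columns
#'   (e.g. the candidate rows of a \code{\link{screen_all}} result).
#' @return sorted character vector of distinct miRNA names.
#' @export
unique_mirnas <- function(records) {
  sort(unique(c(as.character(records$mirna_a), as.character(records$mirna_b))))
}

#' Extract locked classification rules from a screen result
#'
#' @param screen a \code{\link{screen_all}} result.
#' @param candidates_only keep only gated candidate pairs (default).
#' @return list of \code{\link{diffpair_rule}} objects.
#' @export
rules_from_screen <- function(screen, candidates_only = TRUE) {
  df <- if (candidates_only) screen[screen$is_candidate, , drop = FALSE] else screen
  lapply(seq_len(nrow(df)), function(i)
    diffpair_rule(df$mirna_a[i], df$mirna_b[i], df$cutoff[i], df$direction[i]))
}
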