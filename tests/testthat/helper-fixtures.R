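# Build a small ct_matrix from a numeric matrix (auto-names if absent).
make_ct <- function(values, censored = NULL, cycle_limit = 40) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("miR-%02d", seq_len(ncol(values)))
  if (!is.null(censored)) {
    dimnames(censored) <- dimnames(values)
    values[censored] <- cycle_limit
  }
  ct_matrix(values, censored, cycle_limit = cycle_limit)
}

# Metadata for a ct_matrix: first n_cancer samples are cancers.
make_meta <- function(sample_ids, n_cancer, split = "train") {
  data.frame(sample_id = sample_ids,
             group = rep(c("cancer", "control"),
                         c(n_cancer, length(sample_ids) - n_cancer)),
             split = split, stringsAsFactors = FALSE)
}

# Brute-force AUC: loop over every (cancer, control) pair of values.
bf_auc <- function(values, is_cancer) {
  xc <- values[is_cancer]; xo <- values[!is_cancer]
  tot <- 0
  for (a in xc) for (b in xo)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xc) * length(xo))
}

# Brute-force best sens+spec over the midpoint grid and both directions.
bf_best_j <- function(values, is_cancer) {
  v <- sort(unique(values))
  thr <- if (length(v) > 1) c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
         else c(-Inf, Inf)
  best <- 0
  for (t in thr) {
    sens_a <- mean(values[is_cancer] > t); spec_a <- mean(values[!is_cancer] <= t)
    sens_b <- mean(values[is_cancer] < t); spec_b <- mean(values[!is_cancer] >= t)
    best <- max(best, sens_a + spec_a, sens_b + spec_b)
  }
  best
}

# Brute-force two-sided Fisher: sum of hypergeometric point masses not
# exceeding the observed table's, straight from dhyper over the support.
bf_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  d <- dhyper(support, r1, r2, c1)
  sum(d[d <= d[support == tab[1, 1]] * (1 + 1e-7)])
}
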