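test_that("Welch t-test matches stats::t.test across random instances", {
  set.seed(101)
  for (i in 1:12) {
    x <- rnorm(sample(3:15, 1), sd = runif(1, 0.3, 3))
    y <- rnorm(sample(3:15, 1), mean = runif(1, -2, 2), sd = runif(1, 0.3, 3))
    got <- welch_t_test(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch t-test edge behavior: symmetry, identical groups, tiny groups", {
  x <- c(1, 2, 3); y <- c(2, 3, 4, 5)
  a <- welch_t_test(x, y); b <- welch_t_test(y, x)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$df, b$df)
  expect_equal(a$p_value, b$p_value)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  expect_message(z <- welch_t_test(c(2, 2), c(2, 2)), "convention")
  expect_equal(z$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least two")
})

test_that("vectorised Welch agrees with the scalar test per column", {
  set.seed(33)
  xc <- matrix(rnorm(8 * 6, 1), 8, 6)
  xo <- matrix(rnorm(10 * 6), 10, 6)
  vec <- diffpairs:::welch_t_cols(xc, xo)
  for (j in 1:6) {
    ref <- welch_t_test(xc[, j], xo[, j])
    expect_equal(vec$t_stat[j], ref$t_stat)
    expect_equal(vec$df[j], ref$df)
    expect_equal(vec$p_value[j], ref$p_value)
  }
})

test_that("rank AUC equals the brute-force pairwise probability, ties included", {
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    # integer-valued scores force ties regularly
    v <- sample(1:5, n1 + n0, replace = TRUE) + ifelse(runif(1) < 0.5, 0, 0.25)
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    got <- roc_auc(v, lab)
    bf <- bf_auc(v, lab)
    expect_equal(got$auc, max(bf, 1 - bf), tolerance = 1e-12)
    expect_gte(got$auc, 0.5)
    expect_identical(got$direction,
                     if (bf >= 0.5) "cancer_above" else "cancer_below")
  }
})

test_that("AUC endpoints: perfect separation and all-tie degeneracy", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c("cancer", "cancer", "cancer",
                                              "control", "control", "control"))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(rep("cancer", 3), rep("control", 3)))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("cancer", 3)), "both classes")
})

test_that("rank AUC agrees with pROC on a larger random instance", {
  set.seed(77)
  v <- rnorm(60); lab <- rbinom(60, 1, 0.4) == 1
  got <- roc_auc(v, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                        direction = "auto")))
  expect_equal(got$auc, ref, tolerance = 1e-12)
})

test_that("cutoff selection maximizes sens+spec, verified by brute force", {
  set.seed(9)
  for (i in 1:15) {
    v <- round(rnorm(20), 1)
    lab <- c(rep(TRUE, 8), rep(FALSE, 12))
    cs <- select_cutoff(v, lab)
    expect_equal(cs$sens + cs$spec, bf_best_j(v, lab), tolerance = 1e-12)
    # returned sens/spec must be the achieved training values of the rule
    pos <- if (cs$direction == "cancer_above") v > cs$cutoff else v < cs$cutoff
    expect_equal(cs$sens, mean(pos[lab]))
    expect_equal(cs$spec, mean(!pos[!lab]))
  }
})

test_that("cutoff lands on the midpoint under perfect separation", {
  v <- c(5, 6, 7, 1, 2, 3)
  lab <- c(rep(TRUE, 3), rep(FALSE, 3))
  cs <- select_cutoff(v, lab)
  expect_equal(cs$cutoff, 4)
  expect_identical(cs$direction, "cancer_above")
  expect_equal(cs$sens, 1); expect_equal(cs$spec, 1)
})

test_that("sens+spec never falls below the no-information value 1.0", {
  # degenerate all-identical values attain exactly 1.0
  cs <- select_cutoff(rep(3, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(cs$sens + cs$spec, 1)
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(15)
    lab <- sample(c(TRUE, FALSE), 15, replace = TRUE, prob = c(.4, .6))
    if (all(lab) || !any(lab)) next
    cs <- select_cutoff(v, lab)
    expect_gte(cs$sens + cs$spec, 1)
  }
})

test_that("AUC and optimal sens+spec are invariant under monotone transforms", {
  set.seed(14)
  v <- rnorm(24); lab <- c(rep(TRUE, 10), rep(FALSE, 14))
  for (f in list(function(x) exp(x), function(x) 3 * x - 7, function(x) x^3)) {
    expect_equal(roc_auc(f(v), lab)$auc, roc_auc(v, lab)$auc, tolerance = 1e-12)
    a <- select_cutoff(f(v), lab); b <- select_cutoff(v, lab)
    expect_equal(a$sens + a$spec, b$sens + b$spec, tolerance = 1e-12)
  }
})

test_that("a value exactly at the cutoff is classified control", {
  rule <- diffpair_rule("A", "B", 0, "cancer_above")
  expect_identical(diffpairs:::classify_values(rule, c(-1, 0, 1)),
                   c("control", "control", "cancer"))
  rule2 <- diffpair_rule("A", "B", 0, "cancer_below")
  expect_identical(diffpairs:::classify_values(rule2, c(-1, 0, 1)),
                   c("cancer", "control", "control"))
})

test_that("screening ranks a planted perfectly separating pair first", {
  cfg <- simulation_config(n_mirnas = 12, n_cancer_train = 10,
                           n_control_train = 10, n_cancer_test = 1,
                           n_control_test = 1,
                           baseline_sd = 0, sample_shift_sd = 2,
                           noise_sd = 0, n_replicates = 1,
                           effects = data.frame(mirna = 1, effect = 3),
                           seed = 404)
  sim <- simulate_cohort(cfg)
  dp <- compute_diffpairs(sim$replicates[[1]])
  scr <- screen_all(dp, sim$metadata)
  # every pair containing miR-001 separates perfectly; no other pair can
  top <- scr[scr$sens == 1 & scr$spec == 1, ]
  expect_true(all(top$mirna_a == "miR-001" | top$mirna_b == "miR-001"))
  expect_true(scr$mirna_a[1] == "miR-001" | scr$mirna_b[1] == "miR-001")
  expect_equal(scr$sens[1] + scr$spec[1], 2)
  expect_true(scr$is_candidate[1])
})

test_that("the candidate gate consults sensitivity and specificity only", {
  set.seed(31)
  m <- make_ct(matrix(runif(9 * 16, 20, 34), 16, 9))
  dp <- compute_diffpairs(m)
  meta <- make_meta(m$sample_ids, 8)
  scr <- screen_all(dp, meta, sens_min = 0.7, spec_min = 0.7)
  expect_identical(scr$is_candidate, scr$sens >= 0.7 & scr$spec >= 0.7)
  # vacuous gate marks every one of the m(m-1)/2 records a candidate
  scr0 <- screen_all(dp, meta, sens_min = 0, spec_min = 0)
  expect_identical(nrow(scr0), 36L)
  expect_true(all(scr0$is_candidate))
  # ordering contract: descending sens+spec, ties by ascending p
  j <- scr$sens + scr$spec
  expect_true(all(diff(j) <= 1e-12))
})

test_that("screening is invariant to per-sample global Ct offsets end-to-end", {
  set.seed(55)
  ct <- matrix(runif(10 * 6, 22, 34), 10, 6)
  m1 <- make_ct(ct)
  shifted <- sweep(ct, 1, runif(10, -5, 5), `+`)
  dimnames(shifted) <- dimnames(m1$ct)
  meta <- make_meta(m1$sample_ids, 5)
  s1 <- screen_all(compute_diffpairs(m1), meta)
  s2 <- screen_all(compute_diffpairs(make_ct(shifted)), meta)
  expect_equal(s1$auc, s2$auc)
  expect_equal(s1$p_value, s2$p_value)
  expect_equal(s1$cutoff, s2$cutoff)
})

test_that("screen_all requires training samples of both classes", {
  m <- make_ct(matrix(runif(12, 20, 30), 4, 3))
  meta <- make_meta(m$sample_ids, 4)  # no controls
  expect_error(screen_all(compute_diffpairs(m), meta), ">= 2")
})

test_that("unique_mirnas collapses candidate pairs to their member set", {
  recs <- data.frame(mirna_a = c("A", "A"), mirna_b = c("B", "C"))
  expect_identical(unique_mirnas(recs), c("A", "B", "C"))
  expect_identical(unique_mirnas(recs[0, ]), character(0))

  # 140 candidate pairs drawn from 26 planted names collapse back to all 26
  nm <- sprintf("miR-%02d", 1:26)
  all_pairs <- enumerate_pairs(nm)
  set.seed(3)
  cand <- all_pairs[sample(nrow(all_pairs), 140), ]
  expect_identical(unique_mirnas(cand), nm)
})
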