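# diffpairs

Normalization-free discovery and locked-cutoff validation of circulating
miRNA biomarkers from RT-qPCR threshold-cycle (Ct) data.

## The problem

Serum miRNAs are attractive minimally invasive cancer biomarkers, but
absolute qPCR Ct values from serum are confounded by sample-level nuisance:
serum input volume, RNA extraction yield, and reverse-transcription
efficiency shift every Ct in a sample by a common offset, and no consensus
endogenous normalizer exists for serum. The **diffpair** approach sidesteps
normalization entirely: for every unordered pair of miRNAs *(a, b)* it forms
the within-sample difference

> ΔCt(a, b) = Ct(a) − Ct(b),

a log2-scale expression ratio internal to each sample. Any per-sample global
offset γ<sub>s</sub> cancels exactly: (Ct(a)+γ) − (Ct(b)+γ) = ΔCt(a, b).
The price is combinatorial: an m-miRNA panel yields m(m−1)/2 features
(181 miRNAs → 16,290 diffpairs), each screened as a one-dimensional
classifier.

## The method

Two-phase biomarker study design, implemented end to end:

1. **Input & filtering** — Ct tables (samples × miRNAs) with right-censoring
   of undetected targets at the cycle limit (40 cycles); replicate RT
   reactions averaged over detected values; miRNAs undetected in *every*
   sample removed before pairing.
2. **Training screen** — per diffpair: Welch unequal-variance t-test
   (two-sided, Welch–Satterthwaite df), rank-based ROC AUC
   (Mann–Whitney identity, reported ≥ 0.5 with its direction), and a
   Youden-style cutoff chosen over midpoint thresholds to maximize
   sensitivity + specificity. Pairs with training sensitivity ≥ 80% **and**
   specificity ≥ 80% become candidates. P-values are raw; the gate never
   consults them.
3. **Locked validation** — each candidate rule (pair + cutoff + direction)
   is applied *unchanged* to an independent test cohort; performance is
   summarized as sensitivity, specificity, PPV and NPV with exact
   Clopper–Pearson 95% intervals, gated at 75%/75% (boundary inclusive).
4. **Cohort statistics** — two-sided Fisher exact tests (sum of
   hypergeometric point probabilities ≤ the observed table's) for
   demographic balance, e.g. cancer vs smoking history.
5. **Synthetic cohorts** — a seeded generator producing serum-like Ct
   matrices (per-miRNA baselines, per-sample global offsets, planted
   additive disease effects, replicate noise, censoring at 40 cycles) with
   a ground-truth manifest, so the whole pipeline is testable without
   patient data.

## Worked example

```r
library(diffpairs)

cfg <- simulation_config(
  n_mirnas = 24, n_cancer_train = 30, n_control_train = 20,
  n_cancer_test = 55, n_control_test = 75,
  effects = data.frame(mirna = c(1, 2), effect = c(-2.5, 2.5)),
  seed = 42)
sim <- simulate_cohort(cfg)

ct <- filter_globally_undetected(aggregate_replicates(sim$replicates))
dp <- compute_diffpairs(ct)
screen <- screen_all(dp, sim$metadata)           # training split only
head(screen, 3)
#>              pair cutoff    direction auc sens spec  p_value
#> 1 miR-001|miR-002 -3.563 cancer_below   1    1    1 1.49e-32
#> 2 miR-001|miR-015  4.111 cancer_below   1    1    1 3.84e-26
#> 3 miR-001|miR-012 -0.197 cancer_below   1    1    1 5.84e-26

rules <- rules_from_screen(screen)               # 45 candidates at 80/80
val <- validate_candidates(rules, dp, sim$metadata)  # test split, locked cutoffs
head(val, 3)
#>              pair sens spec ppv npv sens_ci_lo  p_value passed_gate
#> 1 miR-001|miR-002    1    1   1   1      0.935 4.35e-74        TRUE
#> 2 miR-001|miR-016    1    1   1   1      0.935 7.42e-61        TRUE
#> 3 miR-001|miR-024    1    1   1   1      0.935 3.48e-57        TRUE
```

The two miRNAs carrying planted effects of ∓2.5 cycles (a ~5.7-fold change
each way) dominate the screen; their mutual pair separates by 5 cycles and
tops both tables. `sens_ci_lo = 0.935` is the exact binomial lower bound for
55/55 test cancers detected. `cohort_association_test(sim$metadata,
"smoker", split = "train")` runs the demographics Fisher test on the same
metadata.

File-based runs mirror this flow: `run_screen()` writes the candidate
table, the locked rules and a run manifest; `run_validate()` consumes the
rules and writes the validation table plus per-pair ROC points. A thin CLI
over both lives at `inst/cli/diffpairs.R` (subcommands `simulate`,
`screen`, `validate`, `cohort-test`).

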