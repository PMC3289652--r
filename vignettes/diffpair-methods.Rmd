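---
title: "Diffpair screening: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffpair screening: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffpairs)
```

## The statistic and its rationale

Serum RT-qPCR gives each sample a vector of threshold-cycle values
$Ct_{s,m}$; lower Ct means more template, and one cycle is roughly a
two-fold abundance difference. Absolute serum Ct values carry a per-sample
nuisance offset $\gamma_s$ (input volume, extraction yield, RT efficiency)
and serum has no accepted endogenous normalizer. The diffpair statistic

$$\Delta Ct_s(a,b) = Ct_{s,a} - Ct_{s,b}$$

is a within-sample log2 expression ratio, and is *algebraically* invariant
to $\gamma_s$ — the package asserts this invariance exactly (`identical()`
on doubles after adding random per-sample offsets), not approximately,
because the cancellation is term-by-term subtraction of the same floating
point value. The cost is that an $m$-miRNA panel becomes
$\binom{m}{2}$ features; at $m = 181$ that is 16,290 one-dimensional
classifiers, which is desk-scale (a dense 130 × 16,290 matrix of doubles
is ~17 MB).

Each diffpair is screened independently on a training cohort:

* **Welch t-test**, two-sided, with fractional Welch–Satterthwaite degrees
  of freedom. The unequal-variance form matters: case and control sera
  routinely differ in dispersion (the motivating data showed a >4-cycle
  spread in controls against ~2 cycles in cancers for the top pair).
* **ROC AUC** through the Mann–Whitney identity (ties counted half), with
  the orientation folded out: AUC is reported $\ge 0.5$ together with the
  direction (`cancer_above`/`cancer_below`) that achieves it.
* **Cutoff selection** maximizing sensitivity + specificity (Youden-style)
  by exhaustive search, described below.
* A candidate gate of **sensitivity ≥ 80% and specificity ≥ 80%**,
  resubstitution values on the training split. The gate consults only
  sensitivity and specificity; p-values are reported raw with no
  multiple-testing correction, which reflects the screening design — the
  protection against selection optimism is the independent validation
  cohort, not an FDR. (Training sensitivity/specificity are assumed to be
  resubstitution values; a cross-validated variant is out of scope.)

Validation applies the trained rule — pair, cutoff, direction — to a
disjoint test cohort with nothing re-fit (`apply_rule` takes no labels, and
the validation table returns the input cutoffs verbatim; both are asserted
in tests). Test performance is gated at 75%/75%, boundary inclusive, and
reported with exact binomial intervals.

## Numerical and procedural conventions

**Threshold grid.** Cutoffs are evaluated at midpoints between adjacent
distinct sorted values, plus $-\infty$/$+\infty$ sentinels. Midpoints make
the selected cutoff well-defined between training samples (any value in the
open interval gives the same training confusion matrix; the midpoint is the
canonical representative) and guarantee no training sample lies on a finite
threshold.

**Boundary.** A sample exactly at the cutoff is classified control. With
midpoint cutoffs this never happens in training; in validation it can, and
fixing the convention keeps locked rules deterministic.

**Tie-breaking.** Several thresholds often achieve the same
sensitivity + specificity. Ties are resolved by (1) larger
min(sensitivity, specificity) — preferring balanced rules, since both
downstream gates are symmetric; (2) smaller |cutoff|; (3) direction
cancer-above; (4) grid order. The hierarchy is arbitrary but total, so the
screen is reproducible bit-for-bit from the input file alone.

**Orientation.** Pairs are canonically oriented by input column order
(stable under renaming, unlike alphabetical order), and a rule stated in
the opposite orientation is the identical classifier after negating the
cutoff and toggling the direction — asserted as a test invariant.

**Censoring.** A target undetected within the cycle limit (40 cycles) is
stored *at* the limit with a censored flag, not as missing. The screen
drops only miRNAs undetected in every sample; partially censored values
enter ΔCt at the clamp. This is a deliberate choice where the field has no
single convention: imputing at the detection limit is conservative (it
understates the separation a truly absent target would give) and keeps
every diffpair computable for every sample. Pairs touching a censored cell
carry an `any_censored` flag so downstream users can filter differently.

**Replicates.** Replicate RT reactions are combined as the mean of
*detected* replicate Ct values; a cell is censored only when all replicates
are censored. Averaging detected values is the qPCR convention; discarding
a detected replicate because its sibling failed would throw away signal.

**Fisher exact test.** Two-sided p is the sum of hypergeometric point
probabilities not exceeding the observed table's ("sum of small p"),
accumulated from log-factorials, with a $1 + 10^{-7}$ relative guard on the
comparison. The definition matters: doubling the one-sided tail gives
0.024, not 0.015, on the training smoking table (9/20 vs 24/30) — only the
sum-of-small-p convention reproduces both published cohort p-values (0.015
and 0.005). Degenerate margins return p = 1 by convention.

**Exact intervals.** Clopper–Pearson via beta quantiles, with endpoints
pinned to 0/1 at $k = 0$/$k = n$. Displayed intervals are rounded
*outward* (`round_ci_outward`): the exact lower bound for 55/55 is
0.9351, which prints as 0.93 — nearest rounding would print 0.94 and
overstate the evidence. (The published specificity interval 0.73–0.91 for
63/75 matches neither Clopper–Pearson (0.737–0.914) nor Wilson (0.741–)
under any standard rounding; the package reproduces the sensitivity bound
and leaves that discrepancy documented rather than reverse-engineered.)

**Percent-to-count reconstruction.** Published demographics report
percentages; `counts_from_percent` inverts them with half-away-from-zero
rounding and warns only when no integer count reproduces the printed
percentage to within half a point (87% of 75 → 65, back-computed 86.7%,
consistent; 10% of 3 is unattainable and warns).

**Display rounding.** Integer percentages use half-away-from-zero
(`round_half_up`), matching how published tables print 0.8209 as 82%.

**Panel size footnote.** A 181-miRNA panel gives
$\binom{181}{2} = 16290$ diffpairs; the package treats 181 as the
authoritative panel size wherever a summary rounds it to 180.

## The synthetic cohort generator

No patient data accompany the motivating study, so the generator is a
first-class module that defines the testbed:

$$Ct(s, m, r) = \beta_m + \gamma_s + \delta_m \mathbf{1}[s \in \text{cancer}] + \varepsilon_{s,m,r}$$

| parameter | default | meaning |
|---|---|---|
| `baseline_ct_mean_range` | 22–36 cycles | span of per-miRNA baseline levels $\beta_m$ (serum miRNAs range from abundant to near the detection limit) |
| `baseline_sd` | 0.8 cycles | jitter of $\beta_m$ around its uniform draw |
| `sample_shift_sd` | 1.5 cycles | per-sample global offset $\gamma_s$ — the nuisance diffpairs cancel; ~3-fold input variation is realistic for serum |
| `effects` | none | planted additive disease effects $\delta_m$ in cycles (2.5 cycles ≈ 5.7-fold) |
| `noise_sd` | 0.5 cycles | per-replicate measurement noise; `noise_df` switches to scaled $t$ for heavy tails |
| `n_replicates` | 2 | independent RT reactions, averaged as in the validation phase |
| `cycle_limit` | 40 | right-censoring limit |
| `censor_fraction_null` | 0 | fraction of miRNAs placed past the limit (undetectable) |

Defaults are stated assumptions chosen once as plausible for serum qPCR,
not fitted to any dataset. The preset `paper_shaped_cohort()` fixes the
two-phase geometry of the motivating study — 181 miRNAs, 30/20 training
and 55/75 test samples, two replicates — with two planted effects of
∓2.5 cycles.

**What it emulates:** per-sample global offsets (so the normalization-free
rationale is actually exercised), replicate structure, right-censoring at
the limit, planted effect sizes on chosen miRNAs, train/test cohort
geometry, and demographics with a cancer-enriched smoking rate so the
cohort Fisher test has signal.

**What it does not emulate:** per-sample *biological* variability of
individual miRNAs (baselines are per-miRNA constants; real sera disperse
each miRNA across subjects beyond measurement noise), correlated miRNA
modules, amplification-efficiency differences, hemolysis and other
pre-analytic artifacts, and batch structure. Group separation in the
simulator is therefore governed by measurement noise alone, which makes
planted effects *easier* to recover than clinical effects of equal
fold-change. Passing the planted-recovery tests demonstrates that the
pipeline's statistics and bookkeeping are correct — it does not predict
clinical performance, and the published test-set operating points are not
reproducible without the original sera.

Determinism is contractual: identical configuration + seed gives
byte-identical cohorts, and the generator restores the caller's RNG
stream.

## Problem sizes in the test suite

The suite favors exhaustive small-instance oracles over large simulations:
Fisher agreement is checked exhaustively for all 2×2 tables with cells
0–4 plus random tables to n = 30 against both a direct `dhyper`
enumeration and `fisher.test`; AUC against a brute-force double loop on up
to 12 samples; cutoff search against brute force at n = 20; interval
coverage with 2,000 binomial draws at n = 75; planted-effect recovery on
12 paper-shaped cohorts; and one full 16,290-pair screen. The complete
suite runs in well under a minute on one core.

## Known limitations

* One pair + one cutoff is the classifier unit; no panels, logistic
  models, or cross-validation (the design under study is a single
  train/test split).
* Clamp-at-limit handling of partial censoring biases ΔCt toward zero for
  weakly expressed targets; rank statistics (AUC) are less affected than
  the t-test.
* PPV/NPV are prevalence-bound to the cohort composition; no projection to
  screening-population prevalence is attempted.
* The Fisher helper covers 2×2 tables only, matching its use for binary
  demographics against case status.
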