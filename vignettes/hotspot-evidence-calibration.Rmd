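---
title: "Calibrating cancer-hotspot overlap as evidence for germline variant pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating cancer-hotspot overlap as evidence for germline variant pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Some proteins drive cancer when mutated somatically and cause rare
Mendelian disorders when the same alteration is constitutional
("oncoprotein duality"; the classic example is HRAS Q61K, a recurrent
somatic driver that causes Costello syndrome as a germline variant).
`oncodual` turns that observation into a calibrated, quantitative line of
evidence for germline missense variant interpretation, in three layers.

**Overlap enrichment.** Germline missense variants are flagged when they
coincide with a recurrent somatic hotspot mutation, either at the
nucleotide level (chromosome, position, reference, alternate allele) or at
the amino-acid-change level, where distinct nucleotide changes producing
the same substitution are grouped. The association between overlap and a
likely pathogenic/pathogenic (LP/P) classification is summarized as a 2x2
odds ratio under progressively more conservative scenarios: comparing LP/P
only against likely benign/benign (LB/B); treating every variant of
uncertain significance (VUS) as if it were benign; and additionally
folding in variants with conflicting interpretations (CIP). The odds ratio
is the cross-product \(OR = ad/bc\) with the Woolf log-scale interval
\(\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})\); a zero cell triggers
the Haldane–Anscombe +0.5 correction (flagged on the estimate). The
default p-value is a Yates-corrected chi-square, with Fisher's exact test
selectable — on tables of this size both land far below any reporting
threshold, and the choice is exposed rather than hidden.

**Evidence strength.** The overlap flag's diagnostic value is its positive
likelihood ratio \(LR^+ = \mathrm{sensitivity}/\mathrm{FPR} =
\frac{a/(a+c)}{b/(b+d)}\), which maps onto the exponential ACMG/AMP point
scale: with odds of pathogenicity \(O\) assigned to very-strong evidence,
the supporting/moderate/strong thresholds are \(O^{1/8}, O^{1/4},
O^{1/2}\). Both common calibrations are provided — \(O = 350\) (moderate
threshold \(350^{1/4} \approx 4.33\)) and the later computational-evidence
calibration \(O = 1124\) (\(\approx 5.79\)). A combining-rule engine
implements the 2015 ACMG/AMP classification table, and
`simulate_upgrades()` counts how many uncertain variants would reach
likely pathogenic if one additional code (say, a moderate-strength
hotspot-overlap criterion) were granted. Contradictory evidence
(pathogenic-side and benign-side combinations both satisfied) resolves to
uncertain.

**Supervised models.** Two models predict pathogenicity from hotspot
context: a weighted logistic regression (overlap flag, gene as a
treatment-coded factor, tumor-sample counts at the change and residue
level, and four conservation scores) and a 350-tree random forest with 4
variables per split, which omits the gene factor and therefore generalizes
beyond the trained genes. The training set treats low-REVEL VUS
(REVEL <= 0.29, the upper bound of benign-supporting computational
evidence) as benign to counter class imbalance, down-weighted by
`1 - REVEL` so that the least-suspicious VUS carry the most weight;
genuine LB/B and LP/P examples carry weight 1.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `revel_cutoff` | 0.29 | strict upper REVEL bound for VUS retained as benign (unitless score in [0,1]) |
| `odds_very_strong` | 350 (alt. 1124) | odds of pathogenicity at very-strong evidence on the exponential scale |
| `n_trees`, `vars_per_split` | 350, 4 | forest size and per-split predictor draw |
| `min_samples` | 25 | strict tumor-sample-count bound for external (COSMIC-style) recurrence filtering |
| `alpha` | 0.05 | two-sided level of the Woolf interval |
| PP3/BP4 cutoffs | 0.644 / 0.290 | REVEL score bands for supporting computational evidence, overridable per tool |

All classification-string mappings (ClinVar vocabulary to internal
labels), column dialects, and contig alias maps are editable config
tables, not hard-coded headers.

## Numerical and design choices

* **Coordinates** are 1-based GRCh37 throughout; chromosome names are
  normalized to have no `chr` prefix. No liftover is attempted.
* **Missing scores stay missing.** Zero is a valid phyloP/REVEL value, so
  absence is `NA`, never 0. VUS with missing REVEL cannot be weighted and
  are dropped from training with a counted reason.
* **Grouping tie rule.** When nucleotide variants of one amino-acid change
  disagree on label, precedence is LP/P > LB/B > VUS (documented,
  overridable); the maximum REVEL and tumor counts in the group are kept.
  The rule is conservative in the direction of keeping established
  pathogenicity.
* **ROC ties.** AUCs use the rank-sum convention with half credit for
  ties, because tumor-sample counts are heavily tied small integers; the
  equality with trapezoidal integration of the tied step curve is a
  package property test. The single operating point is the Youden
  maximizer (the selection criterion is otherwise under-determined).
* **AUPRC** is average precision (step interpolation) by default; linear
  interpolation in PR space is optimistic, but a trapezoid option exists
  for comparability with tools that use it. The F1-optimal threshold
  breaks ties toward the larger threshold, i.e. fewer false positives.
* **Cross-validation folds** are unstratified with a recorded seed (sizes
  differ by at most one); folds that lose a class — or, for the logistic
  model, a gene level — on either side are redrawn up to a retry cap
  rather than silently stratified.
* **Forest weights.** The forest ignores the prior weights: the reference
  implementation takes no case weights, and introducing them would change
  the estimator rather than reproduce it. The logistic model carries the
  weights; for integer weights it is provably identical to fitting
  replicated rows (tested).
* **Separation.** A non-converged logistic fit with fitted probabilities
  pinned at 0/1 is reported at the iteration cap with a warning rather
  than an error; genuine non-convergence without separation is an error.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` draws per-gene variant counts (zero-truncated negative
binomial), class labels at the ClinVar-like composition 6.1% LP/P, 88.5%
VUS, 5.4% LB/B, overlap flags whose log-odds are shifted by the target
log-OR for LP/P variants (so the population odds ratio is exact in
expectation — enrichment is parameterized on the odds scale precisely so
that odds-ratio recovery is unbiased), class-conditional Beta REVEL
scores, four conservation scores driven by a shared latent constraint draw
per variant (hence positively correlated, as real conservation tracks
are), and tumor-sample counts attached only to hotspot mutations, with a
multiplicative inflation for those overlapping pathogenic variants. The
default baseline overlap rate (0.55% of non-LP/P variants) matches the
overlap frequency implied by the published marginals.

The generator does **not** simulate tumor-type composition, sequencing or
annotation error, per-gene pathogenicity priors, linkage between nearby
variants, or the curation sociology that makes real ClinVar labels
partially circular with in-silico scores. Passing tests therefore
demonstrate that the pipeline's statistics are correct and its estimators
recover known generating parameters — not that the models would achieve
any particular accuracy on real cohort data.

Two deliberate test-design consequences follow. First, odds-ratio
recovery is asserted through the full pipeline (generate, annotate,
tabulate, estimate) with interval coverage over seeded replicates.
Second, recovery of the *logistic overlap coefficient* is asserted on
cohorts generated with label-uninformative covariates (no conservation
shift, no pathogenic count inflation): logistic coefficients are
non-collapsible, so conditioning on label-predictive covariates changes
the estimand away from the marginal log odds ratio — with uninformative
covariates the two coincide and the check is exact rather than
approximate.

## Problem sizes

The test suite and analysis scripts run cohorts of roughly 2,000–50,000
variants: interval-coverage and coefficient-recovery checks use ~50,000
variants per replicate (100 and 20 seeded replicates respectively), model
behaviour checks use 1,000–4,000, and the worked analysis uses ~16,000
variants across 60 genes with a 10% held-out split. These sizes give
sampling error comfortably inside the asserted tolerances while keeping a
full run in the minutes range on one core.

## Known limitations

* The exact contingency cells behind the published CIP-folding scenario
  and the most conservative likelihood ratio are not re-derivable from the
  printed marginals alone, so those two numbers are exercised by machinery
  but not asserted.
* The logistic model refuses genes outside its trained levels by design;
  cross-gene prediction is the forest's job.
* The spreadsheet reader consumes delimited exports with an explicit
  column mapping; it does not parse binary spreadsheet formats.
* ACMG combining is implemented at the category-count level; rule variants
  that depend on specific code identities (e.g. PVS1-specific caveats) are
  out of scope.
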