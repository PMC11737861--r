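# oncodual

Recurrent somatic cancer mutations ("hotspots") often strike proteins
whose germline disruption causes rare Mendelian disorders — the same
amino-acid change can be a tumor driver somatically and a developmental
syndrome constitutionally. `oncodual` is an R package for clinical
genomics analysts that converts this overlap into *calibrated* evidence
for germline missense variant interpretation:

* **Overlap enrichment** — annotate ClinVar-style germline variants with
  hotspot overlap (nucleotide- or amino-acid-change-level), tabulate
  overlap against likely pathogenic/pathogenic (LP/P) status under
  progressively conservative scenarios, and estimate the odds ratio
  `OR = ad/bc` with the Woolf interval
  `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))`.
* **Evidence strength** — map the overlap flag's positive likelihood
  ratio `LR+ = (a/(a+c)) / (b/(b+d))` onto the exponential ACMG/AMP point
  scale (thresholds `O^(1/8), O^(1/4), O^(1/2), O` for
  supporting/moderate/strong/very-strong; calibrations `O = 350` and
  `O = 1124`), combine ACMG codes under the 2015 rules, and simulate how
  many VUS one added criterion would upgrade.
* **Supervised models** — a weighted logistic regression (prior weight
  `1 − REVEL` for low-REVEL VUS relabelled benign) and a 350-tree random
  forest (`mtry = 4`) predicting pathogenicity from overlap, tumor-sample
  counts, and conservation scores, with precision-recall/ROC evaluation,
  F1-optimal thresholds, and k-fold cross-validation.
* **Synthetic cohorts** — a generator with controllable overlap
  enrichment on the odds scale, so every stage is testable end-to-end and
  parameter recovery can be asserted without any data download.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort (~16,000 germline variants, 60 genes, overlap enrichment
generated at OR = 28.3):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_filter_hotspots.R
Rscript analysis/03_calibrate_evidence.R
Rscript analysis/04_train_models.R
Rscript analysis/05_evaluate_models.R
```

Step 3 prints the scenario calibration (output as printed by the run
above):

```
LPP_vs_LBB             a=122 b=0 c=825 d=901  OR=267.6 (16.6-4308.7)  LR+=Inf -> very_strong / very_strong
VUS_as_benign          a=122 b=67 c=825 d=14927  OR=32.9 (24.3-44.7)  LR+=28.8 -> strong / moderate
upgrade simulation: 24/67 overlapping VUS (35.8%) would reach likely pathogenic with one added PM
```

Reading: among variants eligible under each scenario, `a` overlapping
LP/P, `b` overlapping comparator, `c`/`d` the non-overlapping rest. In the
conservative scenario that presumes every VUS benign, overlapping
variants still have ~33-fold higher odds of an LP/P classification (the
Woolf 95% CI covers the generating value 28.3), and the likelihood ratio
of 28.8 corresponds to strong evidence under the `O = 350` calibration
and moderate under `O = 1124`. Steps 4–5 then fit and evaluate the two
models:

```
weighted logistic pathogenicity model: 4118 examples, 48 gene levels + 7 predictors
McFadden pseudo-R2 = 0.310, AIC = 2812.7
random-forest pathogenicity model: 350 trees, 4 vars/split, OOB error = 0.146 (seed 42)
LRM: AUPRC = 0.573, AUROC = 0.833, optimal threshold 0.26 (F1 = 0.545)
RFM: AUPRC = 0.513, AUROC = 0.805, optimal threshold 0.30 (F1 = 0.497)
```

Both models rank pathogenic and overlap-carrying variants sharply higher
(probability of superiority 0.81–0.98, rank-sum p ≪ 0.001 in step 4's
output).

In code, the core calibration is three calls:

```r
library(oncodual)
g   <- annotate_overlap(germline, hotspots)          # overlap flags + counts
tab <- build_contingency(g, "VUS_as_benign")         # 2x2 scenario table
odds_ratio(tab)                                      # OR, Woolf CI, p
evidence_strength(as.numeric(positive_likelihood_ratio(tab)),
                  evidence_scale(350))
```

## Layout

```
R/                 package code: variant IO, hotspot filtering, evidence
                   calibration, model pipeline, evaluation, synthetic data
analysis/          numbered narrative drivers for the full workflow
scripts/           acceptance script (see above)
tests/testthat/    unit, property, and acceptance tests
vignettes/         methods vignette: model, assumptions, design choices
```
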