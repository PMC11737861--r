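#!/usr/bin/env Rscript
# Step 4: build the weighted training set (amino-acid-change grouping,
# REVEL <= 0.29 VUS relabelled benign with weight 1 - REVEL, overlap-gene
# whitelist) and fit both pathogenicity models; compare score distributions
# between classes and between overlap strata.

suppressPackageStartupMessages({
  library(oncodual)
  library(jsonlite)
})

germ <- read_germline_table("results/simulated_germline.tsv",
                            label_map = roundtrip_label_map())
hot <- read_hotspot_table("results/simulated_hotspots.tsv")$mutations
ann <- annotate_overlap(germ, hot)

split <- generate_test_split(ann, fraction = 0.1, seed = 7)
ts <- build_training_set(split$training)
message("training-set construction: ",
        paste(names(ts$report), ts$report, sep = "=", collapse = ", "))

lrm <- fit_lrm(ts)
print(lrm)
rfm <- fit_rfm(ts, seed = 42)
print(rfm)

ex <- ts$examples
cmp <- function(scores, grp, what) {
  r <- rank_sum_compare(scores[grp], scores[!grp])
  message(sprintf("  %s: U = %.0f, PS = %.3f, p = %.3g", what, r$U,
                  r$probability_of_superiority, r$p_value))
  list(U = r$U, ps = r$probability_of_superiority, p = r$p_value)
}
message("LRM predicted probabilities:")
lrm_cmp <- list(by_class = cmp(lrm$scores, ex$label == 1, "LP/P vs LB/B/VUS"),
                by_overlap = cmp(lrm$scores, ex$overlap == 1, "overlap present vs absent"))
message("RFM out-of-bag probability scores:")
rfm_cmp <- list(by_class = cmp(rfm$oob_scores, ex$label == 1, "LP/P vs LB/B/VUS"),
                by_overlap = cmp(rfm$oob_scores, ex$overlap == 1, "overlap present vs absent"))

write_json(list(
  construction_report = as.list(ts$report),
  lrm = list(mcfadden_r2 = lrm$mcfadden_r2, aic = lrm$aic,
             n_genes = length(lrm$gene_levels),
             coefficients = as.list(stats::coef(lrm$fit)[c("(Intercept)", "overlap")]),
             comparisons = lrm_cmp),
  rfm = list(oob_error = rfm$oob_error, seed = rfm$seed,
             hyperparams = rfm$hyperparams, comparisons = rfm_cmp)
), "results/04_models.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/04_models.json")
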