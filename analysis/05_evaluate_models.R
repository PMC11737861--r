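#!/usr/bin/env Rscript
# Step 5: evaluate both models on the held-out amino-acid changes
# (precision-recall and ROC, F1-optimal thresholds), cross-validate at the
# reference fold counts (8 for the logistic model, 10 for the forest), and
# benchmark the simulated comparator tool columns.

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
lrm <- fit_lrm(ts)
rfm <- fit_rfm(ts, seed = 42)

# held-out set: grouped, restricted to trained genes, labels binarized the
# same way as in training (retained low-REVEL VUS count as benign)
heldout <- build_training_set(split$heldout, gene_whitelist = ts$gene_whitelist)
te <- heldout$examples
message(sprintf("held-out set: %d grouped variants (%d LP/P)", nrow(te),
                sum(te$label)))

eval_model <- function(model, name) {
  sc <- predict(model, te)
  pr <- pr_curve(sc, te$label)
  roc <- roc_curve(sc, te$label)
  message(sprintf("%s: AUPRC = %.3f, AUROC = %.3f, optimal threshold %.2f (F1 = %.3f)",
                  name, pr$auprc, roc$auroc, pr$optimal_threshold, pr$optimal_f1))
  list(auprc = pr$auprc, auroc = roc$auroc,
       optimal_threshold = pr$optimal_threshold, optimal_f1 = pr$optimal_f1)
}
test_eval <- list(lrm = eval_model(lrm, "LRM"), rfm = eval_model(rfm, "RFM"))

cv_lrm <- cross_validate(ts, "lrm", k = 8, seed = 15)
print(cv_lrm)
cv_rfm <- cross_validate(ts, "rfm", k = 10, seed = 15)
print(cv_rfm)

# comparator in-silico tools carried through the pipeline as score columns
te_records <- split$heldout[split$heldout$gene %in% ts$gene_whitelist &
                              split$heldout$label %in% c("LP_P", "LB_B"), ]
tools <- compare_tools(te_records, te_records$label,
                       c("SIFT", "CADD", "AlphaMissense"))
message("comparator tools on held-out LP/P vs LB/B records:")
for (i in seq_len(nrow(tools))) {
  message(sprintf("  %d. %s: AUPRC = %.3f, AUROC = %.3f (n = %d)",
                  tools$rank[i], tools$tool[i], tools$auprc[i],
                  tools$auroc[i], tools$n_used[i]))
}

write_json(list(
  test_set = test_eval,
  cross_validation = list(
    lrm = list(k = cv_lrm$k, mean_f1 = cv_lrm$mean_f1,
               mean_auprc = cv_lrm$mean_auprc),
    rfm = list(k = cv_rfm$k, mean_f1 = cv_rfm$mean_f1,
               mean_auprc = cv_rfm$mean_auprc)
  ),
  comparator_tools = tools
), "results/05_evaluation.json", auto_unbox = TRUE, digits = NA,
pretty = TRUE)
message("wrote results/05_evaluation.json")
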