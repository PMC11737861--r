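#!/usr/bin/env Rscript
# Step 2: read the simulated tables back through the file interface, filter
# the hotspot set (missense-only, CIP/risk-factor exclusion), and run the
# tumor-sample-count ROC that motivates the >25-sample recurrence cutoff
# for external mutation databases.

suppressPackageStartupMessages({
  library(oncodual)
  library(jsonlite)
})

hot <- read_hotspot_table("results/simulated_hotspots.tsv")
germ <- read_germline_table("results/simulated_germline.tsv",
                            label_map = roundtrip_label_map())
message(sprintf("parsed %d hotspot rows (%d rejected), %d germline records",
                nrow(hot$mutations), nrow(hot$rejected), nrow(germ)))

flt <- filter_hotspots(hot$mutations, germ)
print(flt$report)

# tumor counts of overlapping mutations stratified by LP/P status
ann <- annotate_overlap(germ, flt$mutations)
ov <- ann[ann$overlaps_hotspot, ]
roc <- sample_count_roc(ov$tumor_count_change, ov$label == "LP_P")
message(sprintf("tumor-count ROC on %d overlapping variants: AUC = %.3f, Youden-optimal count > %s",
                nrow(ov), roc$auc, format(roc$optimal_threshold)))

report <- list(
  filter = flt$report[c("n_input", "n_missense", "n_excluded_cip_risk",
                        "n_retained")],
  tumor_count_roc = list(auc = roc$auc,
                         optimal_threshold = roc$optimal_threshold,
                         n_overlapping = nrow(ov))
)
write_json(report, "results/02_filter_report.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
message("wrote results/02_filter_report.json")
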