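#!/usr/bin/env Rscript
# Step 3: the evidence calibration. Scenario contingency tables and odds
# ratios on the simulated cohort, the positive likelihood ratio mapped onto
# the exponential evidence-strength scale under both calibrations (O = 350
# and O = 1124), a VUS-upgrade simulation under one added moderate
# criterion, and REVEL-band accounting for hotspots absent from the
# germline set.

suppressPackageStartupMessages({
  library(oncodual)
  library(jsonlite)
})

germ <- read_germline_table("results/simulated_germline.tsv",
                            label_map = roundtrip_label_map())
hot <- read_hotspot_table("results/simulated_hotspots.tsv")$mutations
ann <- annotate_overlap(germ, hot)

scenarios <- c("LPP_vs_LBB", "VUS_as_benign", "VUS_and_CIP_as_benign")
calib <- lapply(scenarios, function(sc) {
  tab <- tryCatch(build_contingency(ann, sc), error = function(e) NULL)
  if (is.null(tab)) return(NULL)  # CIP stratum can be empty by design
  est <- odds_ratio(tab)
  lr <- positive_likelihood_ratio(tab)
  message(sprintf("%-22s a=%d b=%d c=%d d=%d  OR=%.1f (%.1f-%.1f)  LR+=%.1f -> %s / %s",
                  sc, tab$a, tab$b, tab$c, tab$d, est$odds_ratio, est$ci_low,
                  est$ci_high, as.numeric(lr),
                  evidence_strength(as.numeric(lr), evidence_scale(350)),
                  evidence_strength(as.numeric(lr), evidence_scale(1124))))
  list(scenario = sc, table = tab[c("a", "b", "c", "d")],
       odds_ratio = est$odds_ratio, ci_low = est$ci_low,
       ci_high = est$ci_high, p_value = est$p_value,
       lr_positive = as.numeric(lr),
       band_350 = evidence_strength(as.numeric(lr), evidence_scale(350)),
       band_1124 = evidence_strength(as.numeric(lr), evidence_scale(1124)))
})
calib <- Filter(Negate(is.null), calib)

# what one added moderate-strength criterion would do to a VUS cohort
book <- generate_acmg_codebook(sum(ann$label == "VUS" & ann$overlaps_hotspot),
                               seed = 11)
up <- simulate_upgrades(book, "PM5")
message(sprintf("upgrade simulation: %d/%d overlapping VUS (%.1f%%) would reach likely pathogenic with one added PM",
                up$n_upgraded, length(book), 100 * up$fraction))

# REVEL banding of hotspots with no germline counterpart
absent_key <- !paste(hot$chrom, hot$pos, hot$ref, hot$alt) %in%
  paste(ann$chrom, ann$pos, ann$ref, ann$alt)
revel_proxy <- ann$revel[match(paste(hot$gene, hot$residue), paste(ann$gene, ann$residue))]
bands <- bin_insilico_scores(revel_proxy[absent_key])
message(sprintf("germline-absent hotspots by REVEL band: PP3 %d, indeterminate %d, BP4 %d, missing %d",
                bands["pp3"], bands["indeterminate"], bands["bp4"], bands["missing"]))

write_json(list(scenarios = calib,
                thresholds = list(moderate_350 = unname(evidence_scale(350)$thresholds["moderate"]),
                                  moderate_1124 = unname(evidence_scale(1124)$thresholds["moderate"])),
                upgrade_simulation = up[c("n_upgraded", "fraction")],
                absent_hotspot_revel_bands = as.list(bands)),
           "results/03_calibration.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)
message("wrote results/03_calibration.json")
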