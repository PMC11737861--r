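test_that("overlap annotation matches at the nucleotide and residue-change levels", {
  hot <- make_hotspots(1, gene = "HRAS", chrom = "11", pos = 534286L,
                       ref = "T", alt = "A", residue = 61L,
                       ref_aa = "Q", alt_aa = "K", tcc = 5L, tcr = 9L)
  g <- make_germline(3, gene = "HRAS", chrom = "11",
                     pos = c(534286L, 534286L, 534287L),
                     ref = c("T", "T", "G"), alt = c("A", "C", "T"),
                     residue = 61L, ref_aa = "Q", alt_aa = c("K", "K", "R"))

  nuc <- annotate_overlap(g, hot, mode = "nucleotide")
  expect_equal(nuc$overlaps_hotspot, c(TRUE, FALSE, FALSE))
  expect_equal(nuc$tumor_count_change, c(5L, 0L, 0L))
  expect_equal(nuc$tumor_count_residue, c(9L, 0L, 0L))

  # two distinct SNVs encoding the same amino-acid change both overlap when
  # matching at the residue-change level
  res <- annotate_overlap(g, hot, mode = "residue_change")
  expect_equal(res$overlaps_hotspot, c(TRUE, TRUE, FALSE))
  expect_equal(res$tumor_count_change[2], 5L)
})

test_that("scenario contingency tables partition the eligible records", {
  g <- printed_clinvar_composition()
  t1 <- build_contingency(g, "LPP_vs_LBB")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(426L, 4L, 2723L, 2751L))
  t2 <- build_contingency(g, "VUS_as_benign")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(426L, 265L, 2723L, 47932L))
  expect_equal(t2$a + t2$b + t2$c + t2$d, 51346L)

  # scenarios are nested: the comparator never shrinks from scenario 1 -> 3
  g$label[seq_len(200)] <- "CIP"
  tabs <- lapply(c("LPP_vs_LBB", "VUS_as_benign", "VUS_and_CIP_as_benign"),
                 function(s) build_contingency(g, s))
  comparator <- vapply(tabs, function(t) t$b + t$d, numeric(1))
  expect_true(all(diff(comparator) >= 0))

  expect_error(build_contingency(make_germline(0)[0, ], "LPP_vs_LBB"),
               "no germline records")
  expect_error(build_contingency(make_germline(3, label = "LP_P", overlap = TRUE),
                                 "LPP_vs_LBB"), "empty margin")
  expect_error(build_contingency(make_germline(3, label = "LP_P"), "LPP_vs_LBB"),
               "annotate")
})

test_that("odds ratio uses the cross-product, Woolf CI, and zero-cell correction", {
  flat <- odds_ratio(contingency_table(10, 10, 10, 10))
  expect_equal(flat$odds_ratio, 1.0)
  expect_false(flat$correction_applied)

  # one zero cell: +0.5 everywhere gives (5.5*5.5)/(0.5*5.5) = 11
  corrected <- odds_ratio(contingency_table(5, 0, 5, 5))
  expect_equal(corrected$odds_ratio, 11.0)
  expect_true(corrected$correction_applied)

  set.seed(21)
  for (i in 1:20) {
    cells <- sample(1:400, 4)
    est <- odds_ratio(do.call(contingency_table, as.list(cells)))
    expect_equal(est$odds_ratio, cells[1] * cells[4] / (cells[2] * cells[3]))
    expect_lte(est$ci_low, est$odds_ratio)
    expect_gte(est$ci_high, est$odds_ratio)
    wider <- odds_ratio(do.call(contingency_table, as.list(cells)), alpha = 0.01)
    expect_lte(wider$ci_low, est$ci_low)
    expect_gte(wider$ci_high, est$ci_high)
  }
  expect_error(odds_ratio(contingency_table(0, 0, 5, 5)), "zero margin")
  fisher <- odds_ratio(contingency_table(20, 5, 10, 30), p_method = "fisher")
  expect_equal(fisher$p_value, stats::fisher.test(matrix(c(20, 10, 5, 30), 2))$p.value)
})

test_that("the positive likelihood ratio is sensitivity over false-positive rate", {
  lr <- positive_likelihood_ratio(contingency_table(426, 265, 2723, 47932))
  expect_equal(as.numeric(lr), (426 / 3149) / (265 / 48197), tolerance = 1e-12)
  expect_equal(round(as.numeric(lr), 1), 24.6)
  expect_equal(as.numeric(positive_likelihood_ratio(contingency_table(1, 1, 1, 3))), 2.0)
  expect_equal(as.numeric(positive_likelihood_ratio(contingency_table(0, 5, 5, 5))), 0.0)
  inf <- positive_likelihood_ratio(contingency_table(3, 0, 5, 5))
  expect_true(is.infinite(inf))
  expect_true(attr(inf, "infinite"))
})

test_that("evidence bands follow the exponential point scale", {
  s350 <- evidence_scale(350)
  expect_equal(unname(s350$thresholds),
               c(350^(1 / 8), 350^(1 / 4), 350^(1 / 2), 350))
  expect_equal(round(unname(s350$thresholds["moderate"]), 2), 4.33)
  expect_equal(round(unname(evidence_scale(1124)$thresholds["supporting"]), 2), 2.41)

  # 4.33 <= 18.3 < 18.71, so the conservatively estimated ratio is moderate
  expect_equal(evidence_strength(18.3, s350), "moderate")
  expect_equal(evidence_strength(18.71, s350), "strong")
  expect_equal(evidence_strength(1.5, s350), "none")
  expect_equal(evidence_strength(500, s350), "very_strong")

  for (O in c(2, 10, 350, 1124)) {
    th <- evidence_scale(O)$thresholds
    expect_true(all(diff(th) > 0))
    expect_equal(unname(th), O^(c(1, 2, 4, 8) / 8))
  }
  expect_error(evidence_scale(1), "exceed 1")
})

test_that("the combining engine reproduces the guideline rule examples", {
  expect_equal(acmg_combine(c("PM1", "PM2", "PM4")), "likely_pathogenic")
  expect_equal(acmg_combine(c("PS1", "PM2")), "likely_pathogenic")
  expect_equal(acmg_combine(c("PM2", "PP3")), "uncertain")
  expect_equal(acmg_combine(c("PVS1", "PS1")), "pathogenic")
  expect_equal(acmg_combine("BA1"), "benign")
  expect_equal(acmg_combine(c("BS1", "BP4")), "likely_benign")
  expect_equal(acmg_combine(c("PS1", "PS2", "BA1")), "uncertain")
  expect_equal(acmg_combine(character(0)), "uncertain")
  expect_equal(acmg_combine(c("PM2", "PM2")), "uncertain")  # duplicate dropped
  expect_error(acmg_combine("PX9"), "unknown ACMG code")
})

test_that("upgrade simulation counts match exhaustive re-classification", {
  expect_equal(simulate_upgrades(list(v1 = c("PM2", "PP3")), "PM5")$n_upgraded, 0)
  expect_equal(simulate_upgrades(list(v1 = "PS1"), "PM5")$n_upgraded, 1)
  expect_warning(res <- simulate_upgrades(list(v1 = c("PM5", "PP3"),
                                               v2 = "PS1"), "PM5"),
                 "skipped")
  expect_equal(res$skipped, "v1")
  expect_equal(res$fraction, 1.0)
  expect_error(simulate_upgrades(list(v1 = c("PS1", "PS2")), "PM5"),
               "does not currently classify as uncertain")

  book <- generate_acmg_codebook(10, seed = 4)
  res <- simulate_upgrades(book, "PM5")
  oracle <- sum(vapply(book, function(codes) {
    acmg_combine(c(codes, "PM5")) %in% c("likely_pathogenic", "pathogenic")
  }, logical(1)))
  expect_equal(res$n_upgraded, oracle)
})

test_that("in-silico scores bin into PP3/indeterminate/BP4 bands exactly once", {
  expect_equal(unname(bin_insilico_scores(0.29)["bp4"]), 1L)
  expect_equal(unname(bin_insilico_scores(0.5)["indeterminate"]), 1L)
  expect_equal(unname(bin_insilico_scores(0.644)["pp3"]), 1L)

  set.seed(31)
  scores <- c(stats::runif(10), NA, NA)
  bands <- bin_insilico_scores(scores)
  th <- revel_thresholds()
  expect_equal(unname(bands["pp3"]), sum(scores >= th$pp3_min, na.rm = TRUE))
  expect_equal(unname(bands["bp4"]), sum(scores <= th$bp4_max, na.rm = TRUE))
  expect_equal(unname(bands["missing"]), 2L)
  expect_equal(sum(bands), length(scores))
  expect_error(bin_insilico_scores(0.5, revel_thresholds(pp3_min = 0.2, bp4_max = 0.3)),
               "overlapping")
})
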