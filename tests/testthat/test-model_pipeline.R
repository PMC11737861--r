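test_that("training-set construction applies the REVEL cutoff and prior weights", {
  g <- rbind(
    make_germline(1, label = "LP_P", overlap = TRUE, pos = 1L, residue = 10L),
    make_germline(1, label = "VUS", overlap = FALSE, pos = 2L, residue = 11L,
                  revel = 0.30),
    make_germline(1, label = "VUS", overlap = FALSE, pos = 3L, residue = 12L,
                  revel = 0.10),
    make_germline(1, label = "LB_B", overlap = FALSE, pos = 4L, residue = 13L),
    make_germline(1, label = "VUS", overlap = FALSE, pos = 5L, residue = 14L)
  )
  ts <- build_training_set(g, gene_whitelist = "GENE1")
  ex <- ts$examples
  # VUS at 0.30 excluded (strict cutoff), VUS with missing REVEL excluded
  expect_equal(nrow(ex), 3)
  vus <- ex[ex$residue == 12L, ]
  expect_equal(vus$label, 0L)
  expect_equal(vus$weight, 0.90)
  expect_equal(ex$weight[ex$label == 1L], 1)
  expect_equal(ex$weight[ex$residue == 13L], 1)
})

test_that("nucleotide variants of one amino-acid change group under the tie rule", {
  g <- rbind(
    make_germline(1, label = "LP_P", overlap = TRUE, pos = 1L, residue = 12L,
                  ref_aa = "G", alt_aa = "D", revel = 0.2),
    make_germline(1, label = "VUS", overlap = FALSE, pos = 2L, residue = 12L,
                  ref_aa = "G", alt_aa = "D", revel = 0.9),
    make_germline(1, label = "LB_B", overlap = FALSE, pos = 3L, residue = 50L,
                  ref_aa = "A", alt_aa = "V")
  )
  ts <- build_training_set(g, gene_whitelist = "GENE1")
  ex <- ts$examples
  expect_equal(nrow(ex), 2)  # the two p.G12D records collapse to one
  g12d <- ex[ex$residue == 12L, ]
  expect_equal(g12d$label, 1L)      # LP/P precedence over VUS
  expect_equal(g12d$overlap, 1L)
  expect_equal(ts$report[["n_grouped"]], 2L)
})

test_that("construction report counts telescope", {
  co <- generate_cohort(synthetic_config(seed = 12, n_genes = 10,
                                         variants_per_gene = list(mean = 80, size = 2)))
  g <- annotate_overlap(co$germline, co$hotspots)
  ts <- build_training_set(g)
  r <- ts$report
  expect_equal(r[["n_input"]], nrow(g))
  expect_true(all(diff(r[c("n_input", "n_germline_origin", "n_grouped",
                           "n_classifiable", "n_after_revel_filter",
                           "n_final")]) <= 0))
  expect_equal(r[["n_final"]], nrow(ts$examples))
  expect_equal(r[["n_genes"]], length(unique(ts$examples$gene)))
  expect_error(build_training_set(g, gene_whitelist = character(0)), "empty")
})

test_that("a saturated logit on a 2x2 table recovers the closed-form coefficients", {
  ex <- data.frame(
    gene = "G1",
    overlap = c(1L, 1L, 0L, 0L),
    tumor_count_change = 0L, tumor_count_residue = 0L,
    phylop_mam20 = 0, phylop_vert7 = 0, phastcons_mam20 = 0,
    phastcons_vert7 = 0,
    label = c(1L, 0L, 1L, 0L),
    weight = c(426, 4, 2723, 2751)
  )
  fit <- fit_lrm(ex, use_conservation = FALSE)
  cf <- stats::coef(fit$fit)
  expect_equal(unname(cf["overlap"]), log(426 * 2751 / (4 * 2723)),
               tolerance = 1e-6)
  expect_equal(unname(cf["(Intercept)"]), log(2723 / 2751), tolerance = 1e-6)
})

test_that("uninformative features leave the pseudo-R2 at zero", {
  ex <- data.frame(
    gene = "G1", overlap = 0L, tumor_count_change = 0L,
    tumor_count_residue = 0L, phylop_mam20 = 1, phylop_vert7 = 1,
    phastcons_mam20 = 0.5, phastcons_vert7 = 0.5,
    label = rep(c(0L, 1L), 20), weight = 1
  )
  fit <- fit_lrm(ex)
  expect_equal(fit$mcfadden_r2, 0, tolerance = 1e-8)
})

test_that("integer prior weights are equivalent to row replication", {
  set.seed(3)
  n <- 40
  ex <- data.frame(
    gene = sample(c("A1", "B2"), n, replace = TRUE),
    overlap = stats::rbinom(n, 1, 0.3),
    tumor_count_change = stats::rpois(n, 2),
    tumor_count_residue = stats::rpois(n, 4) + 2,
    phylop_mam20 = stats::rnorm(n), phylop_vert7 = stats::rnorm(n),
    phastcons_mam20 = stats::runif(n), phastcons_vert7 = stats::runif(n),
    label = stats::rbinom(n, 1, 0.5),
    weight = sample(1:3, n, replace = TRUE)
  )
  replicated <- ex[rep(seq_len(n), ex$weight), ]
  replicated$weight <- 1
  f1 <- fit_lrm(ex)
  f2 <- fit_lrm(replicated)
  expect_equal(stats::coef(f1$fit), stats::coef(f2$fit), tolerance = 1e-8)
  expect_equal(f1$mcfadden_r2, f2$mcfadden_r2, tolerance = 1e-8)
})

test_that("the forest separates a linearly separable toy and is seed-deterministic", {
  ex <- make_separable_examples()
  rf <- fit_rfm(ex, seed = 7)
  expect_lte(rf$oob_error, 0.05)
  rf2 <- fit_rfm(ex, seed = 7)
  expect_identical(rf$scores, rf2$scores)
  expect_identical(rf$oob_scores, rf2$oob_scores)

  single <- ex[ex$label == 1, ]
  expect_error(fit_rfm(single), "single class")
  expect_error(fit_rfm(ex, vars_per_split = 10), "vars_per_split")
  expect_error(fit_rfm(ex, n_trees = 0), "n_trees")
})

test_that("prediction honours feature contracts and the gene restriction", {
  ex <- make_separable_examples()
  ex$gene <- rep(c("A1", "B2"), length.out = nrow(ex))
  # the toy is perfectly separable: the fit warns and caps the coefficients
  lrm <- suppressWarnings(fit_lrm(ex))
  expect_equal(predict(lrm, ex), lrm$scores, tolerance = 1e-12)

  unseen <- ex[1:2, ]
  unseen$gene <- "Z9"
  expect_error(predict(lrm, unseen), "Z9")
  expect_error(predict(lrm, ex[, setdiff(names(ex), "phylop_mam20")]),
               "phylop_mam20")

  rf <- fit_rfm(ex, seed = 2)
  path_like <- ex[ex$label == 1, ][1:5, ]
  expect_true(all(predict(rf, path_like) > 0.9))
})

test_that("pathogenic and overlapping variants score higher on enriched synthetic data", {
  cfg <- synthetic_config(seed = 19, n_genes = 12,
                          variants_per_gene = list(mean = 150, size = 3),
                          overlap_base_rate = 0.02)
  co <- generate_cohort(cfg)
  g <- annotate_overlap(co$germline, co$hotspots)
  ts <- build_training_set(g)
  expect_gte(nrow(ts$examples), 500)
  lrm <- fit_lrm(ts)
  ex <- ts$examples
  by_label <- rank_sum_compare(lrm$scores[ex$label == 1], lrm$scores[ex$label == 0])
  by_overlap <- rank_sum_compare(lrm$scores[ex$overlap == 1], lrm$scores[ex$overlap == 0])
  expect_lt(by_label$p_value, 0.05)
  expect_gt(by_label$probability_of_superiority, 0.5)
  expect_lt(by_overlap$p_value, 0.05)
  expect_gt(stats::median(lrm$scores[ex$label == 1]),
            stats::median(lrm$scores[ex$label == 0]))
})

test_that("OOB error stabilizes across seeds as the forest grows", {
  ex <- make_separable_examples(n = 300, seed = 23)
  ex$phylop_mam20 <- ex$phylop_mam20 + stats::rnorm(300, sd = 2)
  oob <- function(ntree, seeds) {
    vapply(seeds, function(s) fit_rfm(ex, n_trees = ntree, seed = s)$oob_error,
           numeric(1))
  }
  small <- oob(15, 1:6)
  large <- oob(300, 1:6)
  expect_lt(stats::sd(large), stats::sd(small) + 1e-9)
})
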