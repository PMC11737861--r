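# Synthetic hotspot + germline cohort generator with the statistical
# structure the analysis assumes: controllable overlap enrichment on the
# odds scale, class-conditional score distributions, and tumor-sample
# counts elevated for pathogenic overlapping variants.

#' Configuration for the synthetic cohort generator
#'
#' Defaults echo the composition of the real germline dataset: class
#' proportions 6.1% LP/P, 88.5% VUS, 5.4% LB/B (the printed 3,149 / 45,442 /
#' 2,755 composition), a baseline overlap rate of 0.55% among non-LP/P
#' variants, and an overlap odds ratio of 28.3 for LP/P variants. REVEL is
#' class-conditional Beta; the four conservation scores share a latent
#' per-variant constraint draw so they are positively correlated, as real
#' conservation tracks are.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param variants_per_gene List `mean`, `size` (negative binomial,
#'   zero-truncated).
#' @param class_proportions Named simplex over LP_P, VUS, LB_B, CIP.
#' @param target_log_or Log odds ratio of (overlap, LP/P); overlap
#'   probability for LP/P variants is the base rate shifted by this amount
#'   on the log-odds scale, so the population odds ratio equals
#'   `exp(target_log_or)` exactly.
#' @param overlap_base_rate Overlap probability for non-LP/P variants.
#' @param revel_by_class Named list of Beta (shape1, shape2) pairs.
#' @param conservation_effect Named numeric: latent constraint shift per class.
#' @param tumor_count_dist List `prob` (zero-truncated geometric success
#'   probability) and `pathogenic_multiplier` (count inflation for
#'   pathogenic overlapping variants).
#' @param revel_missing_rate Fraction of records with missing REVEL.
#' @param clinvar_absent_ratio Hotspots without a germline counterpart,
#'   as a multiple of the overlapping count.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    n_genes = 40,
    variants_per_gene = list(mean = 60, size = 1.5),
    class_proportions = c(LP_P = 0.061, VUS = 0.885, LB_B = 0.054, CIP = 0),
    target_log_or = log(28.3),
    overlap_base_rate = 0.0055,
    revel_by_class = list(LP_P = c(8, 2), VUS = c(2, 2.5), LB_B = c(1.5, 6),
                          CIP = c(2, 3)),
    conservation_effect = c(LP_P = 1.5, VUS = 0.3, LB_B = -0.8, CIP = 0.2),
    tumor_count_dist = list(prob = 0.15, pathogenic_multiplier = 4),
    revel_missing_rate = 0.03,
    clinvar_absent_ratio = 2.5) {
  stopifnot(length(class_proportions) == 4,
            all(c("LP_P", "VUS", "LB_B", "CIP") %in% names(class_proportions)))
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  if (overlap_base_rate <= 0 || overlap_base_rate >= 1) {
    stop("overlap_base_rate must lie in (0,1)")
  }
  p1 <- stats::plogis(stats::qlogis(overlap_base_rate) + target_log_or)
  if (!is.finite(p1) || p1 >= 1 || p1 <= 0) {
    stop("base rate and log odds ratio imply a degenerate overlap probability")
  }
  structure(
    list(seed = seed, n_genes = n_genes,
         variants_per_gene = variants_per_gene,
         class_proportions = class_proportions,
         target_log_or = target_log_or,
         overlap_base_rate = overlap_base_rate,
         revel_by_class = revel_by_class,
         conservation_effect = conservation_effect,
         tumor_count_dist = tumor_count_dist,
         revel_missing_rate = revel_missing_rate,
         clinvar_absent_ratio = clinvar_absent_ratio),
    class = "synthetic_config"
  )
}

rtrunc_geom <- function(n, prob) stats::rgeom(n, prob) + 1L

#' Generate a synthetic hotspot + germline cohort
#'
#' Draws a germline cohort with the configured class proportions, overlap
#' flags calibrated on the odds scale to the target odds ratio,
#' class-conditional REVEL and conservation scores, three comparator tool
#' columns (SIFT, CADD, AlphaMissense) of graded noisiness, and a matching
#' hotspot table: one hotspot per overlapping germline variant at identical
#' coordinates, plus a configurable number of hotspots absent from the
#' germline set. Tumor-sample counts are attached only to hotspots, with a
#' stochastic inflation for those overlapping pathogenic variants. The same
#' seed reproduces the cohort exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list of `hotspots`, `germline` (overlap column left unset; use
#'   [annotate_overlap()]), and `truth` — the realized generating
#'   parameters, including the drawn overlap flags.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  vpg <- pmax(1L, stats::rnbinom(config$n_genes,
                                 mu = config$variants_per_gene$mean,
                                 size = config$variants_per_gene$size))
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  gene <- rep(genes, vpg)
  n <- length(gene)

  classes <- names(config$class_proportions)
  label <- sample(classes, n, replace = TRUE,
                  prob = config$class_proportions)

  p0 <- config$overlap_base_rate
  p_overlap <- stats::plogis(stats::qlogis(p0) +
                               config$target_log_or * (label == "LP_P"))
  overlap <- stats::runif(n) < p_overlap

  shape <- config$revel_by_class
  s1 <- vapply(shape, `[`, numeric(1), 1)[label]
  s2 <- vapply(shape, `[`, numeric(1), 2)[label]
  revel <- stats::rbeta(n, s1, s2)
  revel[stats::runif(n) < config$revel_missing_rate] <- NA_real_

  # shared latent constraint draw per variant -> correlated conservation
  z <- stats::rnorm(n, mean = config$conservation_effect[label], sd = 1)
  phylop_mam20 <- 1.2 * z + stats::rnorm(n, 0, 0.6)
  phylop_vert7 <- 0.9 * z + stats::rnorm(n, 0, 0.6)
  phastcons_mam20 <- stats::pnorm(z + stats::rnorm(n, 0, 0.7))
  phastcons_vert7 <- stats::pnorm(z + stats::rnorm(n, 0, 0.7))

  pathogenic_like <- label == "LP_P"
  sift <- 1 - stats::pnorm(z + stats::rnorm(n, 0, 1.6))
  cadd <- 10 + 6 * z + 8 * pathogenic_like + stats::rnorm(n, 0, 6)
  alpha_missense <- stats::pnorm(0.8 * z + 1.2 * pathogenic_like +
                                   stats::rnorm(n, 0, 0.9))

  n_extra <- round(config$clinvar_absent_ratio * sum(overlap))
  total <- n + n_extra
  pos_pool <- sample.int(2e8, total)
  chrom_pool <- as.character(sample(1:22, total, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  # cyclic offset draws an alternate allele guaranteed to differ from ref
  alt <- bases[(match(ref, bases) - 1 + sample.int(3, total, replace = TRUE)) %% 4 + 1]
  residue <- sample.int(900, total, replace = TRUE)
  ref_aa <- sample(AA_CODES, total, replace = TRUE)
  alt_aa <- AA_CODES[(match(ref_aa, AA_CODES) - 1 +
                        sample.int(19, total, replace = TRUE)) %% 20 + 1]

  allele_origin <- sample(c("germline", "somatic", "unknown"), n,
                          replace = TRUE, prob = c(0.97, 0.015, 0.015))

  germline <- data.frame(
    gene = gene, residue = residue[seq_len(n)], ref_aa = ref_aa[seq_len(n)],
    alt_aa = alt_aa[seq_len(n)], chrom = chrom_pool[seq_len(n)],
    pos = pos_pool[seq_len(n)], ref = ref[seq_len(n)], alt = alt[seq_len(n)],
    label = label, allele_origin = allele_origin, revel = revel,
    phylop_mam20 = phylop_mam20, phylop_vert7 = phylop_vert7,
    phastcons_mam20 = phastcons_mam20, phastcons_vert7 = phastcons_vert7,
    overlaps_hotspot = NA, tumor_count_change = 0L, tumor_count_residue = 0L,
    SIFT = sift, CADD = cadd, AlphaMissense = alpha_missense,
    stringsAsFactors = FALSE
  )

  tc <- config$tumor_count_dist
  ov_idx <- which(overlap)
  tcc_ov <- rtrunc_geom(length(ov_idx), tc$prob)
  mult <- ifelse(label[ov_idx] == "LP_P", tc$pathogenic_multiplier, 1)
  tcc_ov <- as.integer(round(tcc_ov * mult))
  tcr_ov <- tcc_ov + stats::rgeom(length(ov_idx), 0.3)

  extra_idx <- if (n_extra > 0) n + seq_len(n_extra) else integer()
  tcc_ex <- rtrunc_geom(n_extra, tc$prob)
  tcr_ex <- tcc_ex + stats::rgeom(n_extra, 0.3)

  hotspots <- data.frame(
    gene = c(gene[ov_idx],
             sample(genes, n_extra, replace = TRUE)),
    residue = residue[c(ov_idx, extra_idx)],
    ref_aa = ref_aa[c(ov_idx, extra_idx)],
    alt_aa = alt_aa[c(ov_idx, extra_idx)],
    chrom = chrom_pool[c(ov_idx, extra_idx)],
    pos = pos_pool[c(ov_idx, extra_idx)],
    ref = ref[c(ov_idx, extra_idx)],
    alt = alt[c(ov_idx, extra_idx)],
    tumor_count_change = c(tcc_ov, tcc_ex),
    tumor_count_residue = c(as.integer(tcr_ov), as.integer(tcr_ex)),
    stringsAsFactors = FALSE
  )

  truth <- list(config = config, n_variants = n,
                n_per_class = table(label), overlap = overlap,
                p_overlap_base = p0,
                p_overlap_lpp = stats::plogis(stats::qlogis(p0) +
                                                config$target_log_or),
                target_or = exp(config$target_log_or))
  list(hotspots = hotspots, germline = germline, truth = truth)
}

# evidence-code sets that classify as uncertain under the combining rules,
# split by whether one added PM code upgrades them to likely pathogenic
UPGRADABLE_SETS <- list(c("PS1"), c("PM1", "PM2"), c("PM1", "PP2", "PP3"))
NON_UPGRADABLE_SETS <- list(c("PM2", "PP3"), c("PP1", "PP2", "PP3"),
                            c("PM2"), c("PP3"), c("PP1", "PP2"))

#' Generate ACMG code sets for a synthetic VUS cohort
#'
#' Emits per-variant evidence-code sets, every one of which classifies as
#' uncertain under [acmg_combine()]; the mixture of sets that would or
#' would not upgrade to likely pathogenic under one added PM code is
#' controlled by `upgrade_rate`.
#'
#' @param n_vus Number of variants (0 gives an empty map).
#' @param seed Integer seed.
#' @param upgrade_rate Expected fraction drawn from PM-upgradable sets.
#' @return Named list variant -> character vector of codes.
#' @export
generate_acmg_codebook <- function(n_vus, seed = 1, upgrade_rate = 0.265) {
  if (n_vus < 0) stop("n_vus must be non-negative")
  if (n_vus == 0) return(stats::setNames(list(), character()))
  set.seed(seed)
  upgradable <- stats::runif(n_vus) < upgrade_rate
  out <- lapply(upgradable, function(u) {
    pool <- if (u) UPGRADABLE_SETS else NON_UPGRADABLE_SETS
    pool[[sample.int(length(pool), 1)]]
  })
  names(out) <- sprintf("vus_%04d", seq_len(n_vus))
  stopifnot(all(vapply(out, acmg_combine, character(1)) == "uncertain"))
  out
}

#' Split a cohort into training and held-out sets by amino-acid change
#'
#' Splits on the grouped (gene, residue, ref_aa, alt_aa) key so that no
#' amino-acid change appears on both sides — nucleotide variants encoding
#' the same substitution always travel together.
#'
#' @param germline Germline record data.frame.
#' @param fraction Fraction of keys held out (0 < fraction < 1).
#' @param seed Integer seed.
#' @return A list of `training` and `heldout` data.frames.
#' @export
generate_test_split <- function(germline, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0,1)")
  key <- paste(germline$gene, germline$residue, germline$ref_aa,
               germline$alt_aa, sep = "|")
  keys <- unique(key)
  n_hold <- round(length(keys) * fraction)
  if (n_hold == 0 || n_hold == length(keys)) {
    stop("fraction leaves one side of the split empty")
  }
  set.seed(seed)
  hold_keys <- sample(keys, n_hold)
  hold <- key %in% hold_keys
  list(training = germline[!hold, , drop = FALSE],
       heldout = germline[hold, , drop = FALSE])
}
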