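# Fixture builders and independent oracles shared across test files.
# All fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

make_germline <- function(n = 0, gene = "GENE1", label = "VUS",
                          overlap = NA, chrom = "1", pos = NULL,
                          ref = "A", alt = "G", residue = NULL,
                          ref_aa = "Q", alt_aa = "K",
                          revel = NA_real_, origin = "germline") {
  if (n == 0) {
    n <- max(length(gene), length(label), length(pos), length(overlap),
             length(revel), 1)
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(residue)) residue <- seq_len(n)
  data.frame(
    gene = rep_len(gene, n), residue = rep_len(residue, n),
    ref_aa = rep_len(ref_aa, n), alt_aa = rep_len(alt_aa, n),
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    label = rep_len(label, n), allele_origin = rep_len(origin, n),
    revel = rep_len(revel, n),
    phylop_mam20 = stats::rnorm(n), phylop_vert7 = stats::rnorm(n),
    phastcons_mam20 = stats::runif(n), phastcons_vert7 = stats::runif(n),
    overlaps_hotspot = rep_len(overlap, n),
    tumor_count_change = 0L, tumor_count_residue = 0L,
    stringsAsFactors = FALSE
  )
}

make_hotspots <- function(n = 1, gene = "GENE1", chrom = "1", pos = NULL,
                          ref = "A", alt = "G", residue = NULL,
                          ref_aa = "Q", alt_aa = "K", tcc = 5L, tcr = 9L) {
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(residue)) residue <- seq_len(n)
  data.frame(
    gene = rep_len(gene, n), residue = rep_len(residue, n),
    ref_aa = rep_len(ref_aa, n), alt_aa = rep_len(alt_aa, n),
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    tumor_count_change = rep_len(as.integer(tcc), n),
    tumor_count_residue = rep_len(as.integer(tcr), n),
    stringsAsFactors = FALSE
  )
}

# germline records realizing the printed marginals: 691 overlapping
# (426 LP/P, 261 VUS, 4 LB/B) among totals 3,149 / 45,442 / 2,755
printed_clinvar_composition <- function() {
  rbind(
    make_germline(426, label = "LP_P", overlap = TRUE, pos = 1:426),
    make_germline(261, label = "VUS", overlap = TRUE, pos = 500 + 1:261),
    make_germline(4, label = "LB_B", overlap = TRUE, pos = 900 + 1:4),
    make_germline(3149 - 426, label = "LP_P", overlap = FALSE, pos = 1e6 + 1:2723),
    make_germline(45442 - 261, label = "VUS", overlap = FALSE, pos = 2e6 + 1:45181),
    make_germline(2755 - 4, label = "LB_B", overlap = FALSE, pos = 3e6 + 1:2751)
  )
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

make_separable_examples <- function(n = 200, seed = 17) {
  set.seed(seed)
  label <- rep(0:1, each = n / 2)
  data.frame(
    gene = "G1", overlap = label, tumor_count_change = label * 5L,
    tumor_count_residue = label * 6L + 1L,
    phylop_mam20 = stats::rnorm(n, 3 * label),
    phylop_vert7 = stats::rnorm(n, 3 * label),
    phastcons_mam20 = stats::runif(n), phastcons_vert7 = stats::runif(n),
    label = label, weight = 1
  )
}

# --- independent oracles ------------------------------------------------

# average precision from first principles: walk the descending ranking and
# average the precision at each positive item (distinct scores assumed)
ap_oracle <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  hits <- 0
  total <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  total / sum(y)
}

# AUROC by exhaustive pair comparison with half credit for ties
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels != 1]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# trapezoidal area under an ROC polyline given (fpr, tpr) points
trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
}

# ACMG combining rules transcribed independently as a rule table: each row
# is a minimum category-count requirement; a classification applies when
# any of its rows is satisfied
acmg_oracle <- function(codes) {
  codes <- unique(codes)
  cat <- sub("[0-9]*$", "", codes)
  cnt <- function(k) sum(cat == k)
  pvs <- cnt("PVS"); ps <- cnt("PS"); pm <- cnt("PM"); pp <- cnt("PP")
  ba <- cnt("BA"); bs <- cnt("BS"); bp <- cnt("BP")
  req <- function(...) {
    r <- c(...)
    pvs >= r[1] && ps >= r[2] && pm >= r[3] && pp >= r[4]
  }
  p_rules <- list(c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1), c(1, 0, 0, 2),
                  c(0, 2, 0, 0), c(0, 1, 3, 0), c(0, 1, 2, 2), c(0, 1, 1, 4))
  lp_rules <- list(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
                   c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4))
  is_p <- any(vapply(p_rules, function(r) req(r), logical(1)))
  is_lp <- any(vapply(lp_rules, function(r) req(r), logical(1)))
  is_b <- ba >= 1 || bs >= 2
  is_lb <- (bs >= 1 && bp >= 1) || bp >= 2
  if ((is_p || is_lp) && (is_b || is_lb)) return("uncertain")
  if (is_p) return("pathogenic")
  if (is_lp) return("likely_pathogenic")
  if (is_b) return("benign")
  if (is_lb) return("likely_benign")
  "uncertain"
}

# all subsets of size <= k from a code universe (duplicates are dropped by
# the engine anyway, so subsets cover every multiset behaviour)
code_subsets <- function(universe, k) {
  out <- list(character(0))
  for (size in seq_len(k)) {
    cmb <- utils::combn(universe, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
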