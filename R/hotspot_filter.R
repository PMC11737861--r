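# Filtering of hotspot and COSMIC-style mutation tables into the analysis
# set, and the tumor-sample-count ROC threshold procedure.

#' Filter a hotspot mutation table into the analysis set
#'
#' Restricts a raw hotspot table to missense mutations and conservatively
#' excludes any mutation whose corresponding germline variant (matched by
#' chromosome, position, reference and alternate allele) carries a
#' "conflicting interpretations of pathogenicity" or "risk factor"
#' classification.
#'
#' @param mutations Raw hotspot table (data.frame in the
#'   [hotspot_dialect()] columns, as read from file) or the `mutations`
#'   element already produced by [read_hotspot_table()].
#' @param germline Data.frame of germline records carrying `label`.
#' @param dialect Column mapping used when `mutations` is a raw table.
#' @return A list with `mutations` (retained rows, parsed form) and `report`,
#'   a `filter_report` with fields `n_input`, `n_missense`,
#'   `n_excluded_cip_risk`, `n_retained` and `per_gene_counts`.
#' @export
filter_hotspots <- function(mutations, germline, dialect = hotspot_dialect()) {
  if (nrow(mutations) == 0) {
    report <- new_filter_report(0L, 0L, 0L, integer())
    return(list(mutations = mutations[0, , drop = FALSE], report = report))
  }
  if (!"ref_aa" %in% names(mutations)) {
    parsed <- validate_hotspot_rows(mutations, dialect)
    n_input <- nrow(mutations)
    missense <- parsed$mutations
  } else {
    n_input <- nrow(mutations)
    missense <- mutations
  }
  flagged <- germline[germline$label %in% c("CIP", "RISK_FACTOR"), , drop = FALSE]
  key <- function(df) paste(normalize_chrom(df$chrom), df$pos, df$ref, df$alt)
  excluded <- key(missense) %in% key(flagged)
  retained <- missense[!excluded, , drop = FALSE]
  report <- new_filter_report(n_input, nrow(missense), sum(excluded),
                              table(retained$gene))
  list(mutations = retained, report = report)
}

new_filter_report <- function(n_input, n_missense, n_excluded, per_gene) {
  structure(
    list(n_input = as.integer(n_input), n_missense = as.integer(n_missense),
         n_excluded_cip_risk = as.integer(n_excluded),
         n_retained = as.integer(n_missense - n_excluded),
         per_gene_counts = per_gene),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "hotspot filter: %d input rows -> %d missense -> %d retained (%d excluded as CIP/risk-factor), %d genes\n",
    x$n_input, x$n_missense, x$n_retained, x$n_excluded_cip_risk,
    length(x$per_gene_counts)))
  invisible(x)
}

#' ROC analysis of tumor-sample counts against clinical class
#'
#' Evaluates how well the tumor-sample count of an overlapping mutation
#' discriminates likely pathogenic/pathogenic germline variants from the
#' rest. The AUC is the rank-sum statistic U/(n1*n0) with ties contributing
#' one half, equal to the trapezoidal area under the tied ROC step curve.
#' The optimal operating count is the Youden-index (TPR - FPR) maximizer.
#'
#' @param counts Integer vector of tumor-sample counts.
#' @param labels Vector distinguishing LP/P from the comparator: logical,
#'   0/1, or the string `"LP_P"` against anything else.
#' @param min_count Optional; observations with `counts <= min_count` are
#'   removed before the analysis (the restricted high-recurrence ROC).
#' @return A `roc_result`: `points` (threshold, fpr, tpr; sorted by
#'   threshold), `auc`, `optimal_threshold`.
#' @export
sample_count_roc <- function(counts, labels, min_count = NULL) {
  pos <- coerce_binary_labels(labels)
  if (length(counts) != length(pos)) stop("counts and labels differ in length")
  if (!is.null(min_count)) {
    keep <- counts > min_count
    counts <- counts[keep]
    pos <- pos[keep]
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("ROC undefined: only one class present")
  r <- rank(counts)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(counts))
  tpr <- vapply(thr, function(t) mean(counts[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(counts[!pos] >= t), numeric(1))
  # endpoints at -Inf/Inf make the polyline span (1,1) .. (0,0) so that the
  # trapezoidal area of `points` equals the rank-sum AUC under ties
  points <- data.frame(threshold = c(-Inf, thr, Inf), fpr = c(1, fpr, 0),
                       tpr = c(1, tpr, 0))
  youden <- points$tpr - points$fpr
  structure(
    list(points = points, auc = auc,
         optimal_threshold = points$threshold[which.max(youden)]),
    class = "roc_result"
  )
}

coerce_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "LP_P"
}

#' Filter a COSMIC-style mutation table against the hotspot set
#'
#' Retains confirmed-somatic missense mutations observed in strictly more
#' than `min_samples` tumor samples and absent from the hotspot set, where
#' absence is tested at the (gene, protein-change) level — the level at
#' which hotspots are defined — or at the genomic-coordinate level.
#'
#' @param cosmic Data.frame with columns `gene`, `protein_change`,
#'   `sample_count`, and optionally `somatic_status` / coordinate columns.
#' @param hotspots Data.frame of hotspot mutations (parsed form).
#' @param min_samples Strict lower bound on the tumor-sample count.
#' @param match_level `"protein_change"` (default) or `"coordinate"`.
#' @return A list with `mutations` (retained novel recurrent rows),
#'   `per_gene_counts`, and `new_genes` — genes absent from the hotspot gene
#'   list entirely.
#' @export
filter_cosmic <- function(cosmic, hotspots, min_samples = 25,
                          match_level = c("protein_change", "coordinate")) {
  match_level <- match.arg(match_level)
  if (nrow(cosmic) == 0) {
    return(list(mutations = cosmic, per_gene_counts = table(character()),
                new_genes = character()))
  }
  keep <- rep(TRUE, nrow(cosmic))
  if ("somatic_status" %in% names(cosmic)) {
    keep <- keep & grepl("somatic", tolower(cosmic$somatic_status))
  }
  pc <- parse_protein_change(cosmic$protein_change)
  keep <- keep & pc$missense
  count <- suppressWarnings(as.numeric(cosmic$sample_count))
  keep <- keep & !is.na(count) & count > min_samples
  if (match_level == "protein_change") {
    hot_key <- paste(hotspots$gene, hotspots$ref_aa, hotspots$residue,
                     hotspots$alt_aa)
    cos_key <- paste(cosmic$gene, pc$ref_aa, pc$residue, pc$alt_aa)
  } else {
    hot_key <- paste(normalize_chrom(hotspots$chrom), hotspots$pos,
                     hotspots$ref, hotspots$alt)
    cos_key <- paste(normalize_chrom(cosmic$chrom), cosmic$pos, cosmic$ref,
                     cosmic$alt)
  }
  keep <- keep & !(cos_key %in% hot_key)
  retained <- cosmic[keep, , drop = FALSE]
  list(
    mutations = retained,
    per_gene_counts = table(retained$gene),
    new_genes = setdiff(unique(retained$gene), unique(hotspots$gene))
  )
}
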