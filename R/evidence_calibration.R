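# Overlap annotation, scenario contingency tables, odds-ratio and positive
# likelihood-ratio estimation, the exponential ACMG/AMP evidence-strength
# scale, the combining-rule engine, and in-silico score binning.

#' Annotate germline records with hotspot overlap
#'
#' Flags each germline record that coincides with a somatic hotspot
#' mutation, either at the nucleotide level (chromosome, position, reference
#' and alternate allele all equal) or at the amino-acid-change level (gene,
#' residue, reference and alternate residue equal — the grouping under which
#' different nucleotide variants producing the same substitution count as
#' one overlap). Tumor-sample counts of the matched hotspot are copied onto
#' the record; unmatched records get zero counts. When several hotspots
#' match one record (possible in residue-change mode) the maximum counts are
#' kept.
#'
#' @param germline Data.frame of germline records.
#' @param hotspots Data.frame of hotspot mutations (parsed form).
#' @param mode `"nucleotide"` or `"residue_change"`.
#' @return The germline data.frame with `overlaps_hotspot`,
#'   `tumor_count_change` and `tumor_count_residue` filled in.
#' @export
annotate_overlap <- function(germline, hotspots,
                             mode = c("nucleotide", "residue_change")) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    gkey <- paste(normalize_chrom(germline$chrom), germline$pos,
                  germline$ref, germline$alt)
    hkey <- paste(normalize_chrom(hotspots$chrom), hotspots$pos,
                  hotspots$ref, hotspots$alt)
  } else {
    gkey <- paste(germline$gene, germline$residue, germline$ref_aa,
                  germline$alt_aa)
    hkey <- paste(hotspots$gene, hotspots$residue, hotspots$ref_aa,
                  hotspots$alt_aa)
  }
  tcc <- tapply(hotspots$tumor_count_change, hkey, max)
  tcr <- tapply(hotspots$tumor_count_residue, hkey, max)
  idx <- match(gkey, names(tcc))
  germline$overlaps_hotspot <- !is.na(idx)
  germline$tumor_count_change <- ifelse(is.na(idx), 0L, as.integer(tcc[idx]))
  germline$tumor_count_residue <- ifelse(is.na(idx), 0L, as.integer(tcr[idx]))
  germline
}

#' Construct a 2x2 contingency table
#'
#' @param a Overlapping LP/P count. @param b Overlapping comparator count.
#' @param c No-overlap LP/P count. @param d No-overlap comparator count.
#' @param scenario Scenario tag.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d, scenario = "LPP_vs_LBB") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("contingency table is empty")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), scenario = scenario),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table [%s]\n", x$scenario))
  print(matrix(c(x$a, x$c, x$b, x$d), 2, 2,
               dimnames = list(c("overlap", "no overlap"),
                               c("LP/P", "comparator"))))
  invisible(x)
}

#' Build the scenario contingency table from annotated germline records
#'
#' Cross-tabulates hotspot overlap against the LP/P class under one of the
#' comparison scenarios: `LPP_vs_LBB` uses only LP/P and LB/B records;
#' `VUS_as_benign` additionally folds VUS into the comparator (the
#' conservative scenario in which every VUS is presumed benign);
#' `VUS_and_CIP_as_benign` further folds CIP variants in; `gene_subset` is
#' the `VUS_as_benign` comparison restricted to a supplied gene set (used
#' for the mechanism-concordant gene stratum).
#'
#' @param germline Annotated germline records (`overlaps_hotspot` set).
#' @param scenario One of the scenario names above.
#' @param genes Gene subset, required for `scenario = "gene_subset"`.
#' @return A `contingency_table`.
#' @export
build_contingency <- function(germline,
                              scenario = c("LPP_vs_LBB", "VUS_as_benign",
                                           "VUS_and_CIP_as_benign",
                                           "gene_subset"),
                              genes = NULL) {
  scenario <- match.arg(scenario)
  if (nrow(germline) == 0) stop("no germline records")
  if (any(is.na(germline$overlaps_hotspot))) {
    stop("records are not overlap-annotated; run annotate_overlap() first")
  }
  if (scenario == "gene_subset") {
    if (is.null(genes)) stop("scenario 'gene_subset' requires `genes`")
    germline <- germline[germline$gene %in% genes, , drop = FALSE]
  }
  comparator <- switch(scenario,
    LPP_vs_LBB = "LB_B",
    VUS_as_benign = c("LB_B", "VUS"),
    VUS_and_CIP_as_benign = c("LB_B", "VUS", "CIP"),
    gene_subset = c("LB_B", "VUS")
  )
  eligible <- germline[germline$label %in% c("LP_P", comparator), , drop = FALSE]
  is_lpp <- eligible$label == "LP_P"
  ov <- eligible$overlaps_hotspot
  if (sum(is_lpp) == 0 || sum(!is_lpp) == 0) {
    stop(sprintf("scenario '%s' yields an empty margin", scenario))
  }
  contingency_table(sum(ov & is_lpp), sum(ov & !is_lpp),
                    sum(!ov & is_lpp), sum(!ov & !is_lpp),
                    scenario = scenario)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio (a*d)/(b*c) with the Woolf log-scale confidence
#' interval exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell first and
#' flags the estimate. The p-value comes from a two-sided chi-square test
#' with Yates continuity correction on the uncorrected table, or from
#' Fisher's exact test.
#'
#' @param table A `contingency_table`.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @param p_method `"chisq"` (default) or `"fisher"`.
#' @return An `or_estimate`: `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `correction_applied`.
#' @export
odds_ratio <- function(table, alpha = 0.05, p_method = c("chisq", "fisher")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if ((table$a + table$b) == 0 || (table$c + table$d) == 0 ||
      (table$a + table$c) == 0 || (table$b + table$d) == 0) {
    stop("a zero margin leaves the odds ratio undefined even after correction")
  }
  correction <- any(cells == 0)
  w <- if (correction) cells + 0.5 else cells
  or <- (w[1] * w[4]) / (w[2] * w[3])
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(sum(1 / w))
  m <- matrix(cells, 2, 2, byrow = TRUE)
  p <- if (p_method == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = TRUE))$p.value
  }
  structure(
    list(odds_ratio = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
         p_value = p, correction_applied = correction, alpha = alpha),
    class = "or_estimate"
  )
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR = %.3g (%.0f%% CI %.3g-%.3g), p = %.3g%s\n",
              x$odds_ratio, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              x$p_value,
              if (x$correction_applied) " [0.5 correction]" else ""))
  invisible(x)
}

#' Positive likelihood ratio of the overlap flag for LP/P status
#'
#' LR+ = sensitivity / false-positive rate = (a/(a+c)) / (b/(b+d)): how many
#' times more likely an LP/P variant is to overlap a cancer hotspot than a
#' comparator variant is.
#'
#' @param table A `contingency_table`.
#' @return The likelihood ratio; when `b = 0` the value is `Inf` with
#'   attribute `infinite = TRUE`.
#' @export
positive_likelihood_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if ((table$a + table$c) == 0 || (table$b + table$d) == 0) {
    stop("both class margins must be non-empty")
  }
  sens <- table$a / (table$a + table$c)
  fpr <- table$b / (table$b + table$d)
  if (fpr == 0) {
    if (sens == 0) return(structure(NaN, infinite = FALSE))
    return(structure(Inf, infinite = TRUE))
  }
  structure(sens / fpr, infinite = FALSE)
}

#' Exponential ACMG/AMP evidence-strength scale
#'
#' The exponential point scale assigns odds of pathogenicity O to
#' very-strong evidence and O^(1/2), O^(1/4), O^(1/8) to strong, moderate
#' and supporting evidence respectively (points 8, 4, 2, 1 out of 8). The
#' original calibration uses O = 350; a later calibration for computational
#' evidence uses O = 1124.
#'
#' @param odds_very_strong Odds of pathogenicity for very-strong evidence.
#' @return An `evidence_scale` with the four band thresholds.
#' @export
evidence_scale <- function(odds_very_strong = 350) {
  if (!is.numeric(odds_very_strong) || odds_very_strong <= 1) {
    stop("odds_very_strong must exceed 1")
  }
  O <- odds_very_strong
  structure(
    list(odds_very_strong = O,
         thresholds = c(supporting = O^(1 / 8), moderate = O^(1 / 4),
                        strong = O^(1 / 2), very_strong = O)),
    class = "evidence_scale"
  )
}

#' Map a likelihood ratio to an evidence-strength band
#'
#' @param lr Positive likelihood ratio.
#' @param scale An [evidence_scale()].
#' @return One of `"none"`, `"supporting"`, `"moderate"`, `"strong"`,
#'   `"very_strong"` — the highest band whose threshold the ratio meets.
#' @export
evidence_strength <- function(lr, scale = evidence_scale()) {
  stopifnot(inherits(scale, "evidence_scale"), is.numeric(lr), lr > 0)
  bands <- names(scale$thresholds)
  met <- which(scale$thresholds <= lr)
  if (length(met) == 0) "none" else bands[max(met)]
}

ACMG_CATEGORIES <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")

acmg_category <- function(codes) {
  m <- regmatches(codes, regexec("^(PVS|PS|PM|PP|BA|BS|BP)[0-9]*$", codes))
  cat <- vapply(m, function(mi) if (length(mi)) mi[2] else NA_character_,
                character(1))
  if (any(is.na(cat))) {
    stop("unknown ACMG code(s): ", paste(codes[is.na(cat)], collapse = ", "))
  }
  cat
}

#' Combine ACMG/AMP evidence codes into a classification
#'
#' Implements the 2015 ACMG/AMP combining rules. Duplicate code identifiers
#' are dropped before counting. When both a pathogenic-side and a
#' benign-side combination are satisfied, the contradiction resolves to
#' uncertain, as the guideline prescribes.
#'
#' @param codes Character vector of code identifiers (e.g. `c("PS1","PM2")`).
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"uncertain"`,
#'   `"likely_benign"`, `"benign"`.
#' @export
acmg_combine <- function(codes) {
  codes <- unique(as.character(codes))
  if (length(codes) == 0) return("uncertain")
  cat <- acmg_category(codes)
  n <- vapply(ACMG_CATEGORIES, function(k) sum(cat == k), integer(1))
  pvs <- n[["PVS"]]; ps <- n[["PS"]]; pm <- n[["PM"]]; pp <- n[["PP"]]
  ba <- n[["BA"]]; bs <- n[["BS"]]; bp <- n[["BP"]]

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm >= 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps >= 1 && (pm >= 3 || (pm >= 2 && pp >= 2) || (pm >= 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps >= 1 && pm >= 1) ||
    (ps >= 1 && pp >= 2) ||
    pm >= 3 ||
    (pm >= 2 && pp >= 2) ||
    (pm >= 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("uncertain")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "uncertain"
}

#' Simulate upgrades of VUS under an additional evidence code
#'
#' Given the current evidence-code sets of a collection of variants of
#' uncertain significance, counts how many would reach at least a likely
#' pathogenic classification if one further code (e.g. a moderate-strength
#' hotspot-overlap criterion) were added to each.
#'
#' @param vus_codes Named list: variant -> character vector of current codes.
#'   Every entry must currently classify as uncertain.
#' @param added Code identifier to append (e.g. `"PM5"`).
#' @return A list with `n_upgraded`, `fraction` (of evaluable variants),
#'   `upgraded` (names), and `skipped` (variants that already carried the
#'   code, skipped with a warning).
#' @export
simulate_upgrades <- function(vus_codes, added) {
  stopifnot(length(added) == 1)
  acmg_category(added)
  skipped <- character()
  upgraded <- character()
  nms <- names(vus_codes)
  if (is.null(nms)) nms <- as.character(seq_along(vus_codes))
  for (i in seq_along(vus_codes)) {
    codes <- vus_codes[[i]]
    if (acmg_combine(codes) != "uncertain") {
      stop("variant ", nms[i], " does not currently classify as uncertain")
    }
    if (added %in% codes) {
      skipped <- c(skipped, nms[i])
      next
    }
    cls <- acmg_combine(c(codes, added))
    if (cls %in% c("likely_pathogenic", "pathogenic")) {
      upgraded <- c(upgraded, nms[i])
    }
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " variant(s) already carried ", added,
            "; skipped")
  }
  n_eval <- length(vus_codes) - length(skipped)
  list(n_upgraded = length(upgraded),
       fraction = if (n_eval > 0) length(upgraded) / n_eval else NA_real_,
       upgraded = upgraded, skipped = skipped)
}

#' Default REVEL thresholds for PP3/BP4 supporting evidence
#'
#' Benign-supporting evidence (BP4) at REVEL <= 0.290 and
#' pathogenic-supporting (PP3) at REVEL >= 0.644, per the ClinGen-proposed
#' calibration of computational evidence.
#'
#' @param pp3_min,bp4_max Override the cutoffs.
#' @return A list with `pp3_min` and `bp4_max`.
#' @export
revel_thresholds <- function(pp3_min = 0.644, bp4_max = 0.290) {
  list(pp3_min = pp3_min, bp4_max = bp4_max)
}

#' Bin in-silico scores into PP3 / indeterminate / BP4 evidence bands
#'
#' Assigns each score to exactly one band: at least pathogenic-supporting
#' (score >= `pp3_min`), at most benign-supporting (score <= `bp4_max`), or
#' indeterminate. Missing scores are counted separately.
#'
#' @param scores Numeric vector.
#' @param thresholds A threshold list, see [revel_thresholds()].
#' @return Named integer vector with `pp3`, `indeterminate`, `bp4`,
#'   `missing`; bands sum to `length(scores)`.
#' @export
bin_insilico_scores <- function(scores, thresholds = revel_thresholds()) {
  if (thresholds$bp4_max >= thresholds$pp3_min) {
    stop("overlapping threshold bands: bp4_max must be below pp3_min")
  }
  miss <- is.na(scores)
  pp3 <- !miss & scores >= thresholds$pp3_min
  bp4 <- !miss & scores <= thresholds$bp4_max
  c(pp3 = sum(pp3), indeterminate = sum(!miss & !pp3 & !bp4),
    bp4 = sum(bp4), missing = sum(miss))
}
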