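# Domain types, coordinate conventions, and readers/writers for hotspot
# tables, germline variant tables, and cohort VCFs. Coordinates are 1-based,
# fully closed, GRCh37; chromosome names are normalized to have no "chr"
# prefix internally.

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CLASS_LABELS <- c("LP_P", "VUS", "LB_B", "CIP", "RISK_FACTOR", "OTHER")

#' Normalize chromosome names
#'
#' Strips any leading "chr" prefix and applies an optional alias map, so that
#' tables and VCFs with mixed naming conventions can be matched.
#'
#' @param chrom Character vector of chromosome names.
#' @param aliases Optional named character vector mapping observed names to
#'   canonical names (applied after prefix stripping).
#' @return Character vector of canonical chromosome names.
#' @export
normalize_chrom <- function(chrom, aliases = NULL) {
  out <- sub("^chr", "", as.character(chrom))
  if (!is.null(aliases)) {
    hit <- out %in% names(aliases)
    out[hit] <- unname(aliases[out[hit]])
  }
  out
}

#' Parse protein-change notation
#'
#' Parses strings such as `"Q61K"` or `"p.Q61K"` into residue position and
#' one-letter amino-acid codes. A change is missense only when both codes are
#' standard amino acids and differ; nonsense (`*`), synonymous, frameshift and
#' other notations are flagged with a reason.
#'
#' @param x Character vector of protein-change strings.
#' @return A data.frame with columns `residue`, `ref_aa`, `alt_aa`,
#'   `missense` (logical) and `reason` (NA for missense rows).
#' @export
parse_protein_change <- function(x) {
  x0 <- sub("^p\\.", "", trimws(as.character(x)))
  m <- regmatches(x0, regexec("^([A-Za-z\\*])([0-9]+)([A-Za-z\\*=]+)$", x0))
  n <- length(x0)
  out <- data.frame(
    residue = rep(NA_integer_, n), ref_aa = rep(NA_character_, n),
    alt_aa = rep(NA_character_, n), missense = rep(FALSE, n),
    reason = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    mi <- m[[i]]
    if (length(mi) == 0L) {
      out$reason[i] <- sprintf("unparseable protein change '%s'", x0[i])
      next
    }
    ref_aa <- toupper(mi[2])
    alt_aa <- toupper(mi[4])
    out$residue[i] <- as.integer(mi[3])
    out$ref_aa[i] <- ref_aa
    out$alt_aa[i] <- alt_aa
    if (!ref_aa %in% AA_CODES) {
      out$reason[i] <- sprintf("reference residue '%s' is not an amino acid", ref_aa)
    } else if (!alt_aa %in% AA_CODES) {
      out$reason[i] <- sprintf("non-missense change '%s' (alternate '%s')", x0[i], alt_aa)
    } else if (ref_aa == alt_aa) {
      out$reason[i] <- sprintf("synonymous change '%s'", x0[i])
    } else {
      out$missense[i] <- TRUE
    }
  }
  out
}

#' Column dialect for hotspot mutation tables
#'
#' Maps the canonical field names used internally onto the column names of a
#' particular file. Override individual entries to read other dialects.
#'
#' @param gene,protein_change,chrom,pos,ref,alt,tumor_count_change,tumor_count_residue
#'   Column names in the file.
#' @return Named list of column names.
#' @export
hotspot_dialect <- function(gene = "gene", protein_change = "protein_change",
                            chrom = "chrom", pos = "pos", ref = "ref",
                            alt = "alt",
                            tumor_count_change = "tumor_count_change",
                            tumor_count_residue = "tumor_count_residue") {
  list(gene = gene, protein_change = protein_change, chrom = chrom, pos = pos,
       ref = ref, alt = alt, tumor_count_change = tumor_count_change,
       tumor_count_residue = tumor_count_residue)
}

#' Column dialect for germline variant tables
#'
#' @param gene,protein_change,chrom,pos,ref,alt,classification,allele_origin
#'   Column names for the identifying and clinical fields.
#' @param revel,phylop_mam20,phylop_vert7,phastcons_mam20,phastcons_vert7
#'   Column names for the annotation scores.
#' @return Named list of column names.
#' @export
germline_dialect <- function(gene = "gene", protein_change = "protein_change",
                             chrom = "chrom", pos = "pos", ref = "ref",
                             alt = "alt", classification = "classification",
                             allele_origin = "allele_origin", revel = "revel",
                             phylop_mam20 = "phylop_mam20",
                             phylop_vert7 = "phylop_vert7",
                             phastcons_mam20 = "phastcons_mam20",
                             phastcons_vert7 = "phastcons_vert7") {
  list(gene = gene, protein_change = protein_change, chrom = chrom, pos = pos,
       ref = ref, alt = alt, classification = classification,
       allele_origin = allele_origin, revel = revel,
       phylop_mam20 = phylop_mam20, phylop_vert7 = phylop_vert7,
       phastcons_mam20 = phastcons_mam20, phastcons_vert7 = phastcons_vert7)
}

#' Default ClinVar classification-to-label mapping
#'
#' Editable mapping from ClinVar germline classification strings to the
#' internal class labels. Matching is case-insensitive; strings absent from
#' the table map to `OTHER` (or raise an error in strict mode).
#'
#' @return A data.frame with columns `classification` and `label`.
#' @export
clinvar_label_map <- function() {
  data.frame(
    classification = c(
      "pathogenic", "likely pathogenic", "pathogenic/likely pathogenic",
      "benign", "likely benign", "benign/likely benign",
      "uncertain significance",
      "conflicting interpretations of pathogenicity",
      "risk factor"
    ),
    label = c(
      "LP_P", "LP_P", "LP_P",
      "LB_B", "LB_B", "LB_B",
      "VUS",
      "CIP",
      "RISK_FACTOR"
    ),
    stringsAsFactors = FALSE
  )
}

map_class_labels <- function(x, label_map = clinvar_label_map(),
                             strict = FALSE) {
  key <- tolower(trimws(as.character(x)))
  idx <- match(key, tolower(label_map$classification))
  out <- label_map$label[idx]
  unknown <- is.na(idx) & !is.na(key) & nzchar(key)
  if (strict && any(unknown)) {
    stop("unmappable classification string(s): ",
         paste(sQuote(unique(x[unknown])), collapse = ", "))
  }
  out[is.na(out)] <- "OTHER"
  out
}

check_single_base <- function(x, what) {
  bad <- !toupper(as.character(x)) %in% c("A", "C", "G", "T")
  ifelse(bad, sprintf("%s allele '%s' is not a single nucleotide", what, x), NA_character_)
}

#' Read a hotspot mutation table
#'
#' Reads a tab-separated Cancer Hotspots-style table of recurrent somatic
#' mutations. Parsing is total: every input row either becomes a validated
#' hotspot mutation or is reported as a rejection with a reason. Non-missense
#' rows, non-nucleotide alleles, non-numeric counts, and rows violating the
#' count invariant (per-change count must not exceed per-residue count) are
#' rejected; row order of accepted rows is preserved.
#'
#' @param path Path to a TSV file.
#' @param dialect Column mapping, see [hotspot_dialect()].
#' @return A list with `mutations` (data.frame of accepted rows with columns
#'   gene, residue, ref_aa, alt_aa, chrom, pos, ref, alt, tumor_count_change,
#'   tumor_count_residue) and `rejected` (data.frame with `row`, `reason`).
#' @export
read_hotspot_table <- function(path, dialect = hotspot_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols) > 0) {
    stop("hotspot table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_hotspot_rows(raw, dialect)
}

validate_hotspot_rows <- function(raw, dialect = hotspot_dialect()) {
  n <- nrow(raw)
  pc <- parse_protein_change(raw[[dialect$protein_change]])
  reason <- pc$reason
  ref <- toupper(raw[[dialect$ref]])
  alt <- toupper(raw[[dialect$alt]])
  for (chk in list(check_single_base(ref, "reference"),
                   check_single_base(alt, "alternate"))) {
    reason <- ifelse(is.na(reason), chk, reason)
  }
  same <- is.na(reason) & ref == alt
  reason[same] <- "reference and alternate alleles are identical"
  tcc <- suppressWarnings(as.numeric(raw[[dialect$tumor_count_change]]))
  tcr <- suppressWarnings(as.numeric(raw[[dialect$tumor_count_residue]]))
  bad_num <- is.na(reason) & (is.na(tcc) | is.na(tcr))
  reason[bad_num] <- "non-numeric tumor sample count"
  bad_inv <- is.na(reason) & (tcc < 1 | tcc > tcr)
  reason[bad_inv] <- "count invariant violated (1 <= change count <= residue count)"
  pos <- suppressWarnings(as.numeric(raw[[dialect$pos]]))
  bad_pos <- is.na(reason) & (is.na(pos) | pos < 1)
  reason[bad_pos] <- "position is not a positive integer"
  keep <- is.na(reason)
  mutations <- data.frame(
    gene = raw[[dialect$gene]][keep],
    residue = pc$residue[keep],
    ref_aa = pc$ref_aa[keep],
    alt_aa = pc$alt_aa[keep],
    chrom = normalize_chrom(raw[[dialect$chrom]][keep]),
    pos = as.integer(pos[keep]),
    ref = ref[keep],
    alt = alt[keep],
    tumor_count_change = as.integer(tcc[keep]),
    tumor_count_residue = as.integer(tcr[keep]),
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  stopifnot(nrow(mutations) + nrow(rejected) == n)
  list(mutations = mutations, rejected = rejected)
}

#' Read a germline variant table
#'
#' Reads a tab-separated ClinVar-style table of germline missense variants
#' with clinical classifications and in-silico/conservation annotation
#' scores. Classification strings are mapped to class labels via an editable
#' mapping table; unknown strings map to `OTHER` unless `strict = TRUE`.
#' Missing scores stay missing (`NA`), never 0: zero is a valid phyloP and
#' REVEL value. Any column not named in the dialect is carried through
#' unchanged (comparator tool scores such as SIFT or AlphaMissense).
#'
#' @param path Path to a TSV file.
#' @param dialect Column mapping, see [germline_dialect()].
#' @param label_map Classification mapping table, see [clinvar_label_map()].
#' @param strict Error on unmappable classification strings?
#' @return A data.frame of germline records with canonical columns (gene,
#'   residue, ref_aa, alt_aa, chrom, pos, ref, alt, label, allele_origin, the
#'   five scores), `overlaps_hotspot` initialized to `NA` (it is set only by
#'   [annotate_overlap()]), zeroed tumor counts, plus any extra columns.
#' @export
read_germline_table <- function(path, dialect = germline_dialect(),
                                label_map = clinvar_label_map(),
                                strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) return(empty_germline())
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols) > 0) {
    stop("germline table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pc <- parse_protein_change(raw[[dialect$protein_change]])
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  out <- data.frame(
    gene = as.character(raw[[dialect$gene]]),
    residue = pc$residue,
    ref_aa = pc$ref_aa,
    alt_aa = pc$alt_aa,
    chrom = normalize_chrom(raw[[dialect$chrom]]),
    pos = as.integer(num(dialect$pos)),
    ref = toupper(as.character(raw[[dialect$ref]])),
    alt = toupper(as.character(raw[[dialect$alt]])),
    label = map_class_labels(raw[[dialect$classification]], label_map, strict),
    allele_origin = tolower(as.character(raw[[dialect$allele_origin]])),
    revel = num(dialect$revel),
    phylop_mam20 = num(dialect$phylop_mam20),
    phylop_vert7 = num(dialect$phylop_vert7),
    phastcons_mam20 = num(dialect$phastcons_mam20),
    phastcons_vert7 = num(dialect$phastcons_vert7),
    overlaps_hotspot = NA,
    tumor_count_change = 0L,
    tumor_count_residue = 0L,
    stringsAsFactors = FALSE
  )
  out$allele_origin[!out$allele_origin %in% c("germline", "somatic")] <- "unknown"
  for (col in c("revel", "phastcons_mam20", "phastcons_vert7")) {
    bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1)
    if (any(bad)) stop(sprintf("column '%s' has %d value(s) outside [0,1]",
                               col, sum(bad)))
  }
  extras <- setdiff(names(raw), unlist(dialect))
  for (col in extras) out[[col]] <- raw[[col]]
  out
}

empty_germline <- function() {
  data.frame(
    gene = character(), residue = integer(), ref_aa = character(),
    alt_aa = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), label = character(),
    allele_origin = character(), revel = numeric(),
    phylop_mam20 = numeric(), phylop_vert7 = numeric(),
    phastcons_mam20 = numeric(), phastcons_vert7 = numeric(),
    overlaps_hotspot = logical(), tumor_count_change = integer(),
    tumor_count_residue = integer(), stringsAsFactors = FALSE
  )
}

# numbers are written at full precision so that write -> read round-trips
# reproduce every field bit-identically
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  df
}

#' Write a hotspot mutation table
#'
#' Writes the canonical parsed form back to TSV; [read_hotspot_table()] on
#' the result reproduces all fields exactly. Protein changes are re-emitted
#' in compact `Q61K` form.
#'
#' @param mutations Data.frame as returned by [read_hotspot_table()].
#' @param path Output path.
#' @export
write_hotspot_table <- function(mutations, path) {
  out <- data.frame(
    gene = mutations$gene,
    protein_change = paste0(mutations$ref_aa, mutations$residue,
                            mutations$alt_aa),
    chrom = mutations$chrom, pos = mutations$pos, ref = mutations$ref,
    alt = mutations$alt,
    tumor_count_change = mutations$tumor_count_change,
    tumor_count_residue = mutations$tumor_count_residue,
    stringsAsFactors = FALSE
  )
  utils::write.table(format_full_precision(out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a germline variant table
#'
#' Inverse of [read_germline_table()] for annotated or unannotated records;
#' extra comparator-score columns are preserved. Class labels are written
#' as-is (the default label map recognizes them when reading back via
#' an identity mapping added on top of the ClinVar vocabulary).
#'
#' @param germline Data.frame of germline records.
#' @param path Output path.
#' @export
write_germline_table <- function(germline, path) {
  out <- germline
  out$protein_change <- paste0(out$ref_aa, out$residue, out$alt_aa)
  out$classification <- out$label
  keep <- setdiff(names(out), c("residue", "ref_aa", "alt_aa", "label",
                                "overlaps_hotspot", "tumor_count_change",
                                "tumor_count_residue"))
  utils::write.table(format_full_precision(out[, keep, drop = FALSE]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Label map recognizing already-mapped labels
#'
#' Extends [clinvar_label_map()] with identity rows for the internal label
#' vocabulary so that tables written by [write_germline_table()] read back
#' losslessly.
#'
#' @return A data.frame with columns `classification` and `label`.
#' @export
roundtrip_label_map <- function() {
  base <- clinvar_label_map()
  rbind(base, data.frame(classification = CLASS_LABELS, label = CLASS_LABELS,
                         stringsAsFactors = FALSE))
}

#' Query a cohort VCF for hotspot alleles
#'
#' Matches hotspot mutations against a VCF at the allele level: a hotspot
#' matches a record iff chromosome, position, reference and alternate allele
#' all agree exactly. Multi-allelic records are decomposed before matching.
#' Sample identifiers are reported for samples whose genotype carries the
#' matched alternate allele.
#'
#' @param hotspots Data.frame of hotspot mutations.
#' @param vcf_path Path to a VCF (plain text or bgzipped).
#' @param contig_aliases Optional named character vector resolving contig
#'   name mismatches beyond the automatic `chr`-prefix normalization.
#' @return A data.frame with one row per matched hotspot: the hotspot columns
#'   plus `n_samples` and a list-column `samples` of sample identifiers.
#' @export
query_cohort_vcf <- function(hotspots, vcf_path, contig_aliases = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_chrom <- normalize_chrom(fix[, "CHROM"], contig_aliases)
  hk_chrom <- normalize_chrom(hotspots$chrom, contig_aliases)
  unmatched_contigs <- setdiff(unique(hk_chrom), unique(vcf_chrom))
  if (length(unmatched_contigs) > 0) {
    warning("contig(s) absent from VCF (zero matches there): ",
            paste(unmatched_contigs, collapse = ", "))
  }
  gt <- if (ncol(vcf@gt) > 1) vcfR::extract.gt(vcf, element = "GT") else NULL
  matches <- vector("list", nrow(hotspots))
  for (i in seq_len(nrow(hotspots))) {
    hit_rows <- which(vcf_chrom == hk_chrom[i] &
                        as.integer(fix[, "POS"]) == hotspots$pos[i] &
                        toupper(fix[, "REF"]) == hotspots$ref[i])
    samples <- character()
    found <- FALSE
    for (r in hit_rows) {
      alts <- toupper(strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]])
      ai <- which(alts == hotspots$alt[i])  # multi-allelic decomposition
      if (length(ai) == 0) next
      found <- TRUE
      if (!is.null(gt)) {
        g <- gt[r, ]
        carries <- vapply(strsplit(ifelse(is.na(g), "", g), "[/|]"),
                          function(al) as.character(ai[1]) %in% al, logical(1))
        samples <- union(samples, names(g)[carries])
      }
    }
    if (found) {
      row <- hotspots[i, , drop = FALSE]
      row$n_samples <- length(samples)
      row$samples <- I(list(samples))
      matches[[i]] <- row
    }
  }
  matches <- matches[!vapply(matches, is.null, logical(1))]
  if (length(matches) == 0) {
    out <- hotspots[0, , drop = FALSE]
    out$n_samples <- integer()
    out$samples <- I(list())
    return(out)
  }
  do.call(rbind, matches)
}

#' Read a training/test variant sheet with an explicit column mapping
#'
#' Reads a delimited export (CSV or TSV) of a curated training/test variant
#' sheet. Because such sheets have ad-hoc headers, a column mapping from
#' canonical field names to the sheet's column names is required rather than
#' guessed. The canonical fields are those of [germline_dialect()]; any
#' subset may be mapped, and unmapped canonical score fields come back `NA`.
#'
#' @param path Path to a CSV/TSV file (separator inferred from extension,
#'   override with `sep`).
#' @param column_map Named character vector, names = canonical fields,
#'   values = sheet column names. Mandatory.
#' @param sep Field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @param label_map,strict Passed to the classification mapping.
#' @return A germline record data.frame, as [read_germline_table()].
#' @export
read_training_sheet <- function(path, column_map, sep = NULL,
                                label_map = clinvar_label_map(),
                                strict = FALSE) {
  if (missing(column_map) || is.null(column_map) || length(column_map) == 0) {
    stop("a column mapping is required; sheet headers are never guessed")
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from sheet: ",
         paste(missing_cols, collapse = ", "))
  }
  canon <- germline_dialect()
  # rewrite to the canonical dialect, filling unmapped fields with NA
  std <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(canon)) {
    std[[field]] <- if (field %in% names(column_map)) raw[[column_map[[field]]]] else NA
  }
  extras <- setdiff(names(raw), unname(column_map))
  for (col in extras) std[[col]] <- raw[[col]]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(std, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  read_germline_table(tmp, label_map = label_map, strict = strict)
}
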