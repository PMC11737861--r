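test_that("hotspot table parsing is total and enforces the missense and count invariants", {
  raw <- data.frame(
    gene = c("HRAS", "TP53", "KRAS", "BRAF", "EGFR"),
    protein_change = c("Q61K", "R175*", "G12D", "V600E", "L858R"),
    chrom = c("chr11", "17", "12", "7", "7"),
    pos = c(534286, 7578406, 25398284, 140453136, 55259515),
    ref = c("T", "C", "C", "A", "T"),
    alt = c("A", "T", "T", "T", "G"),
    tumor_count_change = c(5, 10, 100, 200, "many"),
    tumor_count_residue = c(9, 12, 120, 150, 60),
    stringsAsFactors = FALSE
  )
  path <- write_tsv(raw)
  res <- read_hotspot_table(path)
  # R175* is nonsense, V600E violates change<=residue count, L858R count not numeric
  expect_equal(nrow(res$mutations), 2)
  expect_equal(nrow(res$rejected), 3)
  expect_equal(nrow(res$mutations) + nrow(res$rejected), nrow(raw))
  expect_match(res$rejected$reason[res$rejected$row == 2], "non-missense")
  expect_match(res$rejected$reason[res$rejected$row == 4], "invariant")

  hras <- res$mutations[1, ]
  expect_equal(hras$gene, "HRAS")
  expect_equal(hras$chrom, "11")  # chr prefix normalized away
  expect_equal(hras$pos, 534286L)
  expect_equal(hras$residue, 61L)
  expect_equal(c(hras$ref_aa, hras$alt_aa), c("Q", "K"))
  expect_equal(hras$tumor_count_change, 5L)
  expect_equal(hras$tumor_count_residue, 9L)

  expect_error(read_hotspot_table(write_tsv(raw[, -1])), "gene")
})

test_that("germline classification strings map onto the label vocabulary", {
  raw <- data.frame(
    gene = "GENE1", protein_change = c("Q61K", "Q61R", "A10V", "A10T", "G5R"),
    chrom = "1", pos = 1:5, ref = "A", alt = "G",
    classification = c("Likely pathogenic", "Pathogenic",
                       "conflicting interpretations of pathogenicity",
                       "Uncertain significance", "curious novel wording"),
    allele_origin = c("germline", "germline", "germline", "somatic", "germline"),
    revel = c(0.9, NA, 0.5, 0.2, 0.1),
    phylop_mam20 = 1, phylop_vert7 = 1, phastcons_mam20 = 0.5,
    phastcons_vert7 = 0.5, stringsAsFactors = FALSE
  )
  g <- read_germline_table(write_tsv(raw))
  expect_equal(g$label, c("LP_P", "LP_P", "CIP", "VUS", "OTHER"))
  expect_equal(g$allele_origin[4], "somatic")
  expect_true(is.na(g$revel[2]))  # missing score stays missing, never 0
  expect_true(all(is.na(g$overlaps_hotspot)))
  expect_error(read_germline_table(write_tsv(raw), strict = TRUE),
               "curious novel wording")
})

test_that("an empty germline file yields an empty record set without error", {
  raw <- data.frame(gene = character(), protein_change = character(),
                    chrom = character(), pos = integer(), ref = character(),
                    alt = character(), classification = character(),
                    allele_origin = character(), revel = numeric(),
                    phylop_mam20 = numeric(), phylop_vert7 = numeric(),
                    phastcons_mam20 = numeric(), phastcons_vert7 = numeric())
  g <- read_germline_table(write_tsv(raw))
  expect_equal(nrow(g), 0)
})

test_that("write then read round-trips hotspot and germline tables bit-identically", {
  set.seed(42)
  co <- generate_cohort(synthetic_config(seed = 42, n_genes = 6,
                                         variants_per_gene = list(mean = 15, size = 2),
                                         overlap_base_rate = 0.05))
  hpath <- tempfile(fileext = ".tsv")
  write_hotspot_table(co$hotspots, hpath)
  back <- read_hotspot_table(hpath)
  expect_equal(nrow(back$rejected), 0)
  expect_identical(back$mutations, co$hotspots[, names(back$mutations)])

  gpath <- tempfile(fileext = ".tsv")
  write_germline_table(co$germline, gpath)
  gback <- read_germline_table(gpath, label_map = roundtrip_label_map())
  for (col in c("gene", "chrom", "pos", "ref", "alt", "residue", "ref_aa",
                "alt_aa", "label", "allele_origin", "revel", "phylop_mam20",
                "phylop_vert7", "phastcons_mam20", "phastcons_vert7",
                "SIFT", "CADD", "AlphaMissense")) {
    expect_identical(gback[[col]], co$germline[[col]], label = col)
  }
})

make_vcf <- function(body, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

test_that("VCF querying matches at the allele level with multi-allelic decomposition", {
  vcf <- make_vcf(c(
    "11\t534286\t.\tT\tA\t.\tPASS\t.\tGT\t0/1\t1|1",
    "12\t1000\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0",
    "7\t2000\t.\tA\tC,T\t.\tPASS\t.\tGT\t0/1\t0/2"
  ))
  hotspots <- make_hotspots(3, gene = c("HRAS", "KRAS", "BRAF"),
                            chrom = c("11", "12", "7"),
                            pos = c(534286L, 1000L, 2000L),
                            ref = c("T", "A", "A"), alt = c("A", "G", "T"))
  res <- query_cohort_vcf(hotspots, vcf)
  # hotspot 1: exact allele in both samples; hotspot 2: same site, different
  # alt -> no match; hotspot 3: second allele of a multi-allelic record
  expect_equal(res$gene, c("HRAS", "BRAF"))
  expect_setequal(res$samples[[1]], c("S1", "S2"))
  expect_equal(res$samples[[2]], "S2")
  expect_equal(res$n_samples, c(2L, 1L))
})

test_that("VCF matching equals a brute-force quadruple comparison", {
  set.seed(9)
  chrom <- sample(c("1", "2"), 12, replace = TRUE)
  pos <- sample(100:120, 12, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "A")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1\t0/0",
                  chrom, pos, ref, alt)
  vcf <- make_vcf(body)
  hot <- make_hotspots(15, chrom = sample(c("1", "2"), 15, replace = TRUE),
                       pos = sample(100:120, 15, replace = TRUE),
                       ref = "A", alt = "G")
  res <- query_cohort_vcf(hot, vcf)
  brute <- vapply(seq_len(nrow(hot)), function(i) {
    any(chrom == hot$chrom[i] & pos == hot$pos[i] &
          ref == hot$ref[i] & alt == hot$alt[i])
  }, logical(1))
  expect_equal(res$pos, hot$pos[brute])
})

test_that("contigs absent from the VCF warn and contribute zero matches", {
  vcf <- make_vcf("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0")
  hot <- make_hotspots(2, chrom = c("1", "X"), pos = c(100L, 100L))
  expect_warning(res <- query_cohort_vcf(hot, vcf), "X")
  expect_equal(nrow(res), 1)
})

test_that("the training-sheet reader requires an explicit column mapping", {
  raw <- data.frame(Symbol = "HRAS", HGVSp = "Q61K", Chr = "11",
                    Position = 534286, Ref = "T", Alt = "A",
                    Class = "Pathogenic", Origin = "germline", REVEL = 0.93)
  path <- tempfile(fileext = ".csv")
  utils::write.table(raw, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_training_sheet(path), "column mapping")
  g <- read_training_sheet(path, column_map = c(
    gene = "Symbol", protein_change = "HGVSp", chrom = "Chr",
    pos = "Position", ref = "Ref", alt = "Alt", classification = "Class",
    allele_origin = "Origin", revel = "REVEL"
  ))
  expect_equal(g$label, "LP_P")
  expect_equal(g$revel, 0.93)
  expect_true(is.na(g$phylop_mam20))
})
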