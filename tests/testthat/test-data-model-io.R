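test_that("matrix dialect parses values losslessly and round-trips", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tS1\tS2",
               "Bacteroides\t60\t10",
               "Prevotella\t5\t30",
               "Faecalibacterium\t12.5\t7.25"), path)
  tab <- read_abundance(path, "matrix")
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(unclass(tab)["S1", "Bacteroides"], 60)
  expect_equal(unclass(tab)["S2", "Faecalibacterium"], 7.25)
  expect_true(all(taxon_rank(tab) == "genus"))

  # write -> read is the identity on values
  out <- tempfile(fileext = ".tsv")
  m <- t(unclass(tab))
  write_table(data.frame(taxon = rownames(m), m, check.names = FALSE), out)
  back <- read_abundance(out, "matrix")
  expect_equal(unclass(back), unclass(tab))
})

test_that("matrix dialect rejects malformed rows and duplicate taxa by line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tS1", "Bacteroides\t60", "Prevotella\t5\t9"), path)
  expect_error(read_abundance(path, "matrix"), "line 3")
  writeLines(c("taxon\tS1", "Bacteroides\t60", "Bacteroides\t5"), path)
  expect_error(read_abundance(path, "matrix"), "duplicate taxon")
  writeLines(c("taxon\tS1", "Bacteroides\tsixty"), path)
  expect_error(read_abundance(path, "matrix"), "line 2")
})

test_that("kraken report parsing keeps the requested rank", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(" 99.00\t990\t0\tD\t2\tBacteria",
               " 60.00\t600\t300\tG\t816\t    Bacteroides",
               " 25.00\t250\t250\tS\t817\t      Bacteroides fragilis",
               " 20.00\t200\t100\tG\t838\t    Prevotella"), path)
  g <- read_abundance(path, "kraken_report", rank = "genus", sample_id = "S1")
  expect_equal(unclass(g)["S1", "Bacteroides"], 60)
  expect_equal(colnames(g), c("Bacteroides", "Prevotella"))
  s <- read_abundance(path, "kraken_report", rank = "species")
  expect_equal(colnames(s), "Bacteroides fragilis")

  # direct-read percent alternative to the clade-percent default
  direct <- read_abundance(path, "kraken_report", rank = "genus",
                           use_clade_percent = FALSE)
  expect_equal(unclass(direct)[1, "Bacteroides"], 100 * 300 / 650)

  # a report with no rows at the requested rank yields an empty table + warning
  path2 <- tempfile(fileext = ".txt")
  writeLines(c(" 25.00\t250\t250\tS\t817\tBacteroides fragilis",
               " 10.00\t100\t100\tS\t853\tFaecalibacterium prausnitzii"), path2)
  n_species_rows <- sum(vapply(strsplit(readLines(path2), "\t"),
                               function(f) f[4] == "S", logical(1)))
  expect_equal(n_species_rows, 2L)
  expect_warning(empty <- read_abundance(path2, "kraken_report", rank = "genus"),
                 "no rows")
  expect_equal(ncol(empty), 0L)
})

test_that("tabular alignments flip reversed reference coordinates", {
  cat <- gene_catalog("vfA", 200)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tvfA\t95.5\t50\t2\t0\t1\t50\t90\t41\t1e-20\t90",
               "r2\tvfA\t88.0\t60\t7\t0\t1\t60\t10\t69\t1e-15\t80"), path)
  hits <- read_alignments(path, "tabular", cat)
  expect_equal(hits$ref_start, c(41L, 10L))
  expect_equal(hits$ref_end, c(90L, 69L))
  expect_equal(hits$identity_pct, c(95.5, 88.0))
  # unknown gene is an error
  writeLines("r1\tnope\t95\t50\t2\t0\t1\t50\t1\t50\t1e-20\t90", path)
  expect_error(read_alignments(path, "tabular", cat), "nope")
})

test_that("SAM identity follows the NM/CIGAR accounting convention", {
  cat <- gene_catalog("geneA", 500)
  sam <- write_sam(c(
    "r1\t0\tgeneA\t1\t60\t100M\t*\t0\t0\t*\t*\tNM:i:5",
    "r2\t0\tgeneA\t101\t60\t50M10I40M\t*\t0\t0\t*\t*\tNM:i:12",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), c(geneA = 500L))
  hits <- read_alignments(sam, "sam", cat)
  expect_equal(nrow(hits), 2L)                       # unmapped skipped
  expect_equal(hits$identity_pct[hits$read_id == "r1"], 95.0)
  # 90 M columns; NM 12 includes the 10 inserted bases -> 2 mismatches
  expect_equal(hits$identity_pct[hits$read_id == "r2"], 100 * (90 - 2) / 90)
  expect_equal(hits$ref_start[hits$read_id == "r2"], 101L)
  expect_equal(hits$ref_end[hits$read_id == "r2"], 190L)
})

test_that("SAM and tabular agree on paired fixtures of the same alignment", {
  cat <- gene_catalog("geneA", 500)
  # 100M with 5 mismatches starting at reference position 11
  sam <- write_sam("r1\t0\tgeneA\t11\t60\t100M\t*\t0\t0\t*\t*\tNM:i:5",
                   c(geneA = 500L))
  tab <- tempfile(fileext = ".tsv")
  writeLines("r1\tgeneA\t95.0\t100\t5\t0\t1\t100\t11\t110\t1e-30\t150", tab)
  h_sam <- read_alignments(sam, "sam", cat)
  h_tab <- read_alignments(tab, "tabular", cat)
  expect_equal(h_sam$identity_pct, h_tab$identity_pct)
  expect_equal(h_sam$ref_start, h_tab$ref_start)
  expect_equal(h_sam$ref_end, h_tab$ref_end)
})

test_that("SAM records lacking NM fall back to MD or fail loudly", {
  cat <- gene_catalog("geneA", 500)
  sam <- write_sam("r1\t0\tgeneA\t1\t60\t100M\t*\t0\t0\t*\t*\tMD:Z:40A9C49",
                   c(geneA = 500L))
  hits <- read_alignments(sam, "sam", cat)
  expect_equal(hits$identity_pct, 98.0)
  sam2 <- write_sam("r1\t0\tgeneA\t1\t60\t100M\t*\t0\t0\t*\t*",
                    c(geneA = 500L))
  expect_error(read_alignments(sam2, "sam", cat), "NM")
  expect_warning(h <- read_alignments(sam2, "sam", cat, on_missing_nm = "skip"),
                 "skipped")
  expect_equal(nrow(h), 0L)
})

test_that("secondary alignments are kept by default and excludable", {
  cat <- gene_catalog("geneA", 500)
  sam <- write_sam(c(
    "r1\t0\tgeneA\t1\t60\t100M\t*\t0\t0\t*\t*\tNM:i:0",
    "r1\t256\tgeneA\t201\t0\t100M\t*\t0\t0\t*\t*\tNM:i:1"), c(geneA = 500L))
  expect_equal(nrow(read_alignments(sam, "sam", cat)), 2L)
  expect_equal(nrow(read_alignments(sam, "sam", cat,
                                    include_secondary = FALSE)), 1L)
})

test_that("metadata reading validates the design and keeps extras", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tregion\tlocation\tparticipant_id\tmonth_index\tshoe_size",
               "S1\tR1\tR1L1\tP1\t1\t42",
               "S2\tR1\tR1L1\tP1\t2\t42",
               "S3\tR2\tR2L1\tP2\t\t38"), path)
  meta <- read_metadata(path)
  expect_s3_class(meta, "sample_metadata")
  expect_equal(nrow(meta), 3L)
  expect_equal(meta$shoe_size, c(42L, 42L, 38L))   # unknown extras retained
  expect_true(is.na(meta$month_index[3]))

  # duplicate sample id
  writeLines(c("sample_id\tregion", "S1\tR1", "S1\tR2"), path)
  expect_error(read_metadata(path), "duplicate sample_id")
  # location mapped to two regions breaks the nesting invariant
  writeLines(c("sample_id\tregion\tlocation",
               "S1\tR1\tLocX", "S2\tR2\tLocX"), path)
  expect_error(read_metadata(path), "more than one region")
})

test_that("gene screen results round-trip through TSV", {
  cat <- simulate_gene_catalog(n_genes = 5, seed = 2)
  truth <- data.frame(sample_id = "S1", gene_id = cat$gene_id,
                      coverage = c(1, 0.95, 0.5, 0, 0.99),
                      identity = c(99, 95, 99, NA, 85), label = "x")
  hits <- simulate_gene_hits(truth, cat, seed = 3)
  res <- screen_cohort(hits, cat)
  path <- tempfile(fileext = ".tsv")
  write_table(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$coverage_pct, res$coverage_pct)
  expect_equal(back$present, res$present)
})

test_that("gene catalogs read from FASTA with class assignment", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">blaOXA-85_1_JANA01000064 beta-lactamase", "ACGTACGTAC",
               ">tet32_2_EF626943", "GGGTTTAAACC"), fa)
  cat <- read_gene_catalog(fa, read_class_map())
  expect_equal(cat$gene_id, c("blaOXA-85_1_JANA01000064", "tet32_2_EF626943"))
  expect_equal(cat$length_bp, c(10L, 11L))
  expect_equal(cat$class_label, c("beta-lactam", "tetracycline"))
})
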