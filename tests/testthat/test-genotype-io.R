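test_that("read_vcf counts alt alleles, maps ./. to missing, ignores phasing", {
  path <- write_tiny_vcf(list(
    list(chrom = "chr1", pos = 100, id = "rs1", ref = "A", alt = "G",
         gts = c("0/0", "0/1", "1|1", "./.")),
    list(chrom = "chr1", pos = 200, id = "rs2", ref = "C", alt = "T",
         gts = c("0|0", "1/0", "0/0", "1/1"))),
    samples = c("s1", "s2", "s3", "s4"))
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(unname(gm$dosages[, "rs1"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(gm$dosages[, "rs2"]), c(0L, 1L, 0L, 2L))
  expect_equal(gm$variants$pos, c(100L, 200L))
  expect_equal(gm$variants$alt, c("G", "T"))
})

test_that("read_vcf all-reference single call gives dosage 0", {
  path <- write_tiny_vcf(list(
    list(chrom = "chr1", pos = 5, id = "rs9", ref = "A", alt = "G",
         gts = "0/0")), samples = "only")
  gm <- read_vcf(path)
  expect_equal(unname(gm$dosages), matrix(0L, 1, 1))
})

test_that("read_vcf rejects multi-allelic sites naming them, and non-diploid GT", {
  multi <- write_tiny_vcf(list(
    list(chrom = "chr1", pos = 10, id = "rsM", ref = "A", alt = "G,T",
         gts = c("0/0", "0/1"))), samples = c("a", "b"))
  expect_error(read_vcf(multi), "rsM")
  haploid <- write_tiny_vcf(list(
    list(chrom = "chr1", pos = 10, id = "rsH", ref = "A", alt = "G",
         gts = c("0", "1"))), samples = c("a", "b"))
  expect_error(read_vcf(haploid), "diploid")
})

test_that("read_dosage_table parses codes, NA, and rejects bad cells", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\trs2", "s1\t0\tNA", "s2\t2\t1"), path)
  gm <- read_dosage_table(path)
  expect_equal(unname(gm$dosages), matrix(c(0L, 2L, NA, 1L), 2, 2))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\t3"), bad)
  expect_error(read_dosage_table(bad), "'3'.*'s1'.*'rs1'")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\t0", "s1\t1"), dup)
  expect_error(read_dosage_table(dup), "duplicate sample id")
})

test_that("dosage-table round trip reproduces a genotype matrix exactly", {
  gm <- random_gm(12, 7, seed = 5, miss_rate = 0.15)
  p <- tempfile(fileext = ".tsv"); m <- tempfile(fileext = ".tsv")
  write_dosage_table(gm, p, m)
  back <- read_dosage_table(p, m)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$variants$variant_id, gm$variants$variant_id)
  expect_identical(back$variants$pos, gm$variants$pos)
  expect_identical(back$sample_ids, gm$sample_ids)
})

test_that("read_vcf and read_dosage_table of equivalent content agree", {
  gm <- random_gm(8, 5, seed = 11, miss_rate = 0.1)
  vp <- tempfile(fileext = ".vcf")
  write_vcf(gm, vp)
  tp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_dosage_table(gm, tp, mp)
  a <- read_vcf(vp); b <- read_dosage_table(tp, mp)
  common <- colnames(b$dosages)
  expect_identical(a$dosages[, common], b$dosages[, common])
})

test_that("read_gene_intervals parses BED4, merges duplicates, validates", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr16\t31102175\t31106118\tVKORC1", p)
  g <- read_gene_intervals(p)
  expect_equal(as.data.frame(g),
               data.frame(symbol = "VKORC1", chrom = "chr16",
                          start = 31102175L, end = 31106118L,
                          stringsAsFactors = FALSE))

  empty <- tempfile(fileext = ".bed"); writeLines(character(0), empty)
  expect_equal(nrow(read_gene_intervals(empty)), 0L)

  degenerate <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tG1", degenerate)
  expect_error(read_gene_intervals(degenerate), "start >= end")

  narrow <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", narrow)
  expect_error(read_gene_intervals(narrow), "fewer than 4")

  merged <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200\tG1", "chr2\t150\t400\tG1"), merged)
  g2 <- read_gene_intervals(merged)
  expect_equal(g2$start, 100L); expect_equal(g2$end, 400L)

  split <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200\tG1", "chr3\t150\t400\tG1"), split)
  expect_error(read_gene_intervals(split), "multiple chromosomes")
})

test_that("read_gene_list dedups, drops unknown symbols, errors when empty", {
  p <- tempfile()
  writeLines(c("VKORC1", "CYP2C9", "CYP2C9", "# a comment"), p)
  expect_equal(read_gene_list(p), c("VKORC1", "CYP2C9"))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr16\t31102175\t31106118\tVKORC1", bed)
  genes <- read_gene_intervals(bed)
  p2 <- tempfile(); writeLines(c("VKORC1", "NOSUCH"), p2)
  expect_warning(got <- read_gene_list(p2, genes), "NOSUCH")
  expect_equal(got, "VKORC1")

  p3 <- tempfile(); writeLines("#comment only", p3)
  expect_error(read_gene_list(p3), "removed all genes")
})

test_that("read_phenotypes reconciles by id and validates doses", {
  gm <- random_gm(3, 2, seed = 1)
  p <- tempfile(fileext = ".tsv")
  # deliberately shuffled relative to the genotype sample order
  writeLines(c("sample_id\tdose_mg_per_day",
               "s003\t7.5", "s001\t2.0", "s002\t4.25"), p)
  phen <- read_phenotypes(p, gm)
  expect_equal(phen$sample_id, gm$sample_ids)
  expect_equal(phen$dose, c(2.0, 4.25, 7.5))

  extra <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tdose_mg_per_day",
               "s001\t2", "s002\t4", "s003\t7", "ghost\t5"), extra)
  expect_error(read_phenotypes(extra, gm), "ghost")
  expect_warning(ph2 <- read_phenotypes(extra, gm, drop_extra = TRUE), "ghost")
  expect_equal(nrow(ph2), 3L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tdose_mg_per_day", "s001\t0"), bad)
  expect_error(read_phenotypes(bad), "> 0")
})

test_that("genotype_matrix validates its invariants", {
  v <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 1L,
                  ref = "A", alt = "G")
  expect_error(genotype_matrix(matrix(3L, 1, 1), v, "s1"), "out of")
  expect_error(genotype_matrix(matrix(0L, 2, 1), v, c("s1", "s1")),
               "duplicate sample")
  v2 <- rbind(v, v)
  expect_error(genotype_matrix(matrix(0L, 1, 2), v2, "s1"),
               "duplicate variant")
  expect_error(genotype_matrix(matrix(0L, 1, 1), v, c("s1", "s2")), "rows")
})
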