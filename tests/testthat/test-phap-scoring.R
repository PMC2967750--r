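one_variant_gm <- function(col, id = "rs1") {
  genotype_matrix(matrix(as.integer(col), ncol = 1),
                  data.frame(variant_id = id, chrom = "chr1", pos = 100L,
                             ref = "A", alt = "G"),
                  sprintf("s%d", seq_along(col)))
}

test_that("estimate_frequencies counts genotypes and alleles over non-missing", {
  f <- estimate_frequencies(one_variant_gm(c(0, 0, 0, 0)))
  expect_equal(c(f$f_geno0, f$f_geno1, f$f_geno2), c(1, 0, 0))
  expect_equal(f$f_alt, 0)

  f2 <- estimate_frequencies(one_variant_gm(c(0, 0, 1, 2)))
  expect_equal(c(f2$f_geno0, f2$f_geno1, f2$f_geno2), c(0.5, 0.25, 0.25))
  expect_equal(f2$f_alt, 3 / 8)

  f3 <- estimate_frequencies(one_variant_gm(c(0, 1, NA, 1)))
  expect_equal(c(f3$f_geno0, f3$f_geno1, f3$f_geno2), c(1 / 3, 2 / 3, 0))
  expect_equal(f3$n_observed, 3L)

  expect_error(estimate_frequencies(one_variant_gm(c(NA, NA))), "rs1")
})

test_that("frequency invariants hold on random matrices", {
  for (seed in 1:5) {
    gm <- random_gm(30, 10, seed = seed, miss_rate = 0.2)
    f <- estimate_frequencies(gm)
    expect_equal(f$f_geno0 + f$f_geno1 + f$f_geno2, rep(1, 10))
    expect_equal(f$f_ref + f$f_alt, rep(1, 10))
    # every observed genotype has frequency >= 1/n_observed
    for (k in 1:10) {
      obs <- gm$dosages[, k]; obs <- obs[!is.na(obs)]
      for (code in unique(obs)) {
        expect_gte(f[k, paste0("f_geno", code)], 1 / f$n_observed[k] - 1e-12)
      }
    }
  }
})

test_that("phap_score closed forms: all-frequency-1 gives 0; ln 8 example", {
  gm <- one_variant_gm(c(0, 0, 0))
  f <- estimate_frequencies(gm)
  expect_equal(phap_score(c(rs1 = 0L), f, "rs1")$score, 0)

  # two SNPs with patient-genotype frequencies 0.5 and 0.25
  gm2 <- genotype_matrix(
    matrix(c(0L, 0L, 1L, 2L,   1L, 0L, 0L, 2L), ncol = 2),
    data.frame(variant_id = c("a", "b"), chrom = "chr1", pos = c(1L, 2L),
               ref = "A", alt = "G"),
    c("p1", "p2", "p3", "p4"))
  f2 <- estimate_frequencies(gm2)
  # patient p1: code 0 at a (freq 0.5), code 1 at b (freq 0.25)
  expect_equal(phap_score(gm2$dosages["p1", ], f2, c("a", "b"))$score,
               log(8), tolerance = 1e-12)
})

test_that("missing genotypes contribute 0 and are tallied", {
  gm <- genotype_matrix(
    matrix(c(0L, 1L, 1L, NA, 2L, 0L), ncol = 2),
    data.frame(variant_id = c("a", "b"), chrom = "chr1", pos = c(1L, 2L),
               ref = "A", alt = "G"),
    c("p1", "p2", "p3"))
  f <- estimate_frequencies(gm)
  ps <- phap_score(gm$dosages["p1", ], f, c("a", "b"))
  expect_equal(ps$n_missing, 1L)
  expect_equal(ps$score, -log(f["a", "f_geno0"]))
  # all-missing patient scores 0
  expect_equal(phap_score(c(a = NA, b = NA), f, c("a", "b"))$score, 0)
})

test_that("score_matrix equals brute force, both modes, with sharing", {
  for (seed in 1:4) {
    sim <- simulate_cohort(sim_config(n_samples = 15, n_genes = 4,
                                      snps_per_gene = c(2, 5), seed = seed))
    gm <- sim$genotypes
    set.seed(seed)
    gm$dosages[sample(length(gm$dosages), 10)] <- NA
    map <- assign_snps(gm$variants, sim$genes)
    for (mode in c("genotype", "allele")) {
      gsm <- score_matrix(gm, map, mode = mode)
      for (g in names(map$gene_variants)) for (i in c(1, 7, 15)) {
        expect_equal(gsm$scores[i, g],
                     brute_phap(gm, i, map$gene_variants[[g]], mode),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a SNP shared by two genes contributes to both scores", {
  genes <- structure(data.frame(
    symbol = c("A", "B"), chrom = "chr1",
    start = c(0L, 150L), end = c(200L, 400L), stringsAsFactors = FALSE),
    class = c("gene_intervals", "data.frame"))
  gm <- genotype_matrix(
    matrix(c(0L, 1L, 2L,  1L, 1L, 0L,  2L, 0L, 0L), ncol = 3),
    data.frame(variant_id = c("vA", "vShared", "vB"), chrom = "chr1",
               pos = c(100L, 180L, 300L), ref = "A", alt = "G"),
    c("p1", "p2", "p3"))
  map <- assign_snps(gm$variants, genes, window_bp = 0)
  gsm <- score_matrix(gm, map)
  for (i in 1:3) {
    expect_equal(gsm$scores[i, "A"], brute_phap(gm, i, c("vA", "vShared")),
                 tolerance = 1e-12)
    expect_equal(gsm$scores[i, "B"], brute_phap(gm, i, c("vShared", "vB")),
                 tolerance = 1e-12)
  }
})

test_that("scores are non-negative, additive over partitions, monotone in rarity", {
  gm <- random_gm(20, 6, seed = 8)
  f <- estimate_frequencies(gm)
  ids <- gm$variants$variant_id
  for (i in c(1, 10, 20)) {
    whole <- phap_score(gm$dosages[i, ], f, ids)$score
    expect_gte(whole, 0)
    part <- phap_score(gm$dosages[i, ids[1:2]], f, ids[1:2])$score +
      phap_score(gm$dosages[i, ids[3:6]], f, ids[3:6])$score
    expect_equal(whole, part, tolerance = 1e-12)
  }
  # lowering the frequency of a patient's genotype raises the score:
  # hand-build two frequency tables differing at one SNP
  f2 <- f
  code <- gm$dosages[1, 1]
  col <- paste0("f_geno", code)
  f2[1, col] <- f2[1, col] / 2
  expect_gt(phap_score(gm$dosages[1, ], f2, ids)$score,
            phap_score(gm$dosages[1, ], f, ids)$score)
})

test_that("the sole alt-hom carrier has the maximal gene score", {
  set.seed(13)
  d <- matrix(sample(0:1, 60, replace = TRUE), nrow = 20, ncol = 3)
  d[5, 2] <- 2L  # unique alt-hom carrier at SNP 2
  d[-5, 2] <- 0L
  gm <- genotype_matrix(d, data.frame(
    variant_id = c("x", "y", "z"), chrom = "chr1", pos = 1:3 * 10L,
    ref = "A", alt = "G"), sprintf("s%02d", 1:20))
  f <- estimate_frequencies(gm)
  scores <- vapply(1:20, function(i)
    phap_score(gm$dosages[i, ], f, c("x", "y", "z"))$score, numeric(1))
  expect_equal(which.max(scores), 5L)
})

test_that("zero external frequency errors without a floor, clamps with one", {
  gm <- one_variant_gm(c(0, 1, 1))
  f <- estimate_frequencies(gm)
  f$f_geno2 <- 0  # external table claiming alt-hom never occurs
  expect_error(phap_score(c(rs1 = 2L), f, "rs1"), "floor")
  ps <- phap_score(c(rs1 = 2L), f, "rs1", freq_floor = 1e-4)
  expect_equal(ps$score, -log(1e-4))
})
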