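# shared fixture builders; everything is generated in code at test time

# minimal VCF writer for hand-crafted sites: `sites` is a list of lists
# with chrom, pos, id, ref, alt, gts (character vector per sample)
write_tiny_vcf <- function(sites, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(sites, function(s) {
    paste(c(s$chrom, s$pos, s$id, s$ref, s$alt, ".", ".", ".", "GT", s$gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# random small genotype matrix with optional missingness
random_gm <- function(n_samples, n_variants, seed, miss_rate = 0,
                      chrom = "chr1") {
  set.seed(seed)
  d <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE),
              nrow = n_samples)
  if (miss_rate > 0) {
    d[stats::runif(length(d)) < miss_rate] <- NA
  }
  chroms <- rep_len(chrom, n_variants)
  genotype_matrix(
    d,
    data.frame(variant_id = sprintf("v%03d", seq_len(n_variants)),
               chrom = chroms, pos = seq_len(n_variants) * 100L,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    sprintf("s%03d", seq_len(n_samples)))
}

# independent count-log-sum brute force for the pHap score of one
# patient/gene; deliberately naive, shares no code with the package path
brute_phap <- function(gm, sample_idx, variant_ids, mode = "genotype") {
  s <- 0
  for (v in variant_ids) {
    d <- gm$dosages[sample_idx, v]
    if (is.na(d)) next
    col <- gm$dosages[, v]
    obs <- col[!is.na(col)]
    if (mode == "genotype") {
      s <- s - log(sum(obs == d) / length(obs))
    } else {
      fa <- sum(obs) / (2 * length(obs))
      if (d >= 1) s <- s - d * log(fa)
      if (d <= 1) s <- s - (2 - d) * log(1 - fa)
    }
  }
  s
}

# cohort with one planted effect gene; baseline compensated so the dose
# distribution stays centred instead of drifting with the burden mean
planted_cohort <- function(n_samples, n_genes, h2, effect_gene = 1L,
                           seed = 1L, maf_range = c(0.05, 0.5), ...) {
  base <- sim_config(n_samples = n_samples, n_genes = n_genes,
                     maf_range = maf_range, seed = seed, ...)
  beta <- effect_beta_for_variance(base, h2)
  eb <- mean(base$snps_per_gene) * 2 * mean(maf_range)
  cfg <- sim_config(n_samples = n_samples, n_genes = n_genes,
                    maf_range = maf_range, seed = seed,
                    effect_genes = data.frame(gene = effect_gene, beta = beta),
                    baseline_dose = max(5 - beta * eb, 1), ...)
  simulate_cohort(cfg)
}

# map + score a simulated cohort in one call
score_cohort <- function(sim, mode = "genotype") {
  map <- assign_snps(sim$genotypes$variants, sim$genes)
  score_matrix(sim$genotypes, map, mode = mode)
}

fixture_dir <- function() system.file("extdata", "cohort60",
                                      package = "phapscore")
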