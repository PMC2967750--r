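#' Configuration for a synthetic pharmacogenomic cohort
#'
#' Describes a desk-scale warfarin-like cohort with known ground truth.
#' Defaults mirror the scale of a small dose-response GWAS: 181 patients,
#' a 50-gene candidate panel, common-variant allele frequencies, a mean
#' maintenance dose near 5 mg/day with noise chosen so the low (<= 3) and
#' high (>= 7) tails are populated, and no planted effect unless asked.
#'
#' @param n_samples number of patients (default 181).
#' @param n_genes number of candidate genes (default 50).
#' @param snps_per_gene inclusive integer range (length-2) of SNP counts
#'   per gene (default `c(4, 12)`).
#' @param maf_range minor-allele-frequency range, within (0, 0.5]
#'   (default `c(0.05, 0.5)`).
#' @param ld_rho probability that a SNP's haplotype allele copies its
#'   gene neighbour's, inducing local LD (default 0 = none).
#' @param effect_genes data.frame (`gene`, `beta`) or NULL: planted
#'   per-minor-allele dose effects, mg/day per allele, by gene index or
#'   symbol.
#' @param baseline_dose intercept dose in mg/day (default 5).
#' @param noise_sd Gaussian dose noise SD in mg/day (default 2).
#' @param low_threshold,high_threshold extreme-dose cutoffs in mg/day
#'   (defaults 3 and 7).
#' @param seed RNG seed (default 1).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 181L, n_genes = 50L,
                       snps_per_gene = c(4L, 12L),
                       maf_range = c(0.05, 0.5), ld_rho = 0,
                       effect_genes = NULL, baseline_dose = 5,
                       noise_sd = 2, low_threshold = 3,
                       high_threshold = 7, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              maf_range = as.numeric(maf_range), ld_rho = as.numeric(ld_rho),
              effect_genes = effect_genes,
              baseline_dose = as.numeric(baseline_dose),
              noise_sd = as.numeric(noise_sd),
              low_threshold = as.numeric(low_threshold),
              high_threshold = as.numeric(high_threshold),
              seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_samples >= 2, "n_samples must be >= 2")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(length(cfg$snps_per_gene) == 2 && all(cfg$snps_per_gene >= 1) &&
        cfg$snps_per_gene[1] <= cfg$snps_per_gene[2],
      "snps_per_gene must be an increasing pair of positive integers")
  chk(length(cfg$maf_range) == 2 && all(cfg$maf_range > 0) &&
        all(cfg$maf_range <= 0.5) && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range must lie within (0, 0.5]")
  chk(cfg$ld_rho >= 0 && cfg$ld_rho < 1, "ld_rho must be in [0, 1)")
  chk(cfg$noise_sd > 0, "noise_sd must be > 0")
  chk(cfg$baseline_dose > 0, "baseline_dose must be > 0")
  chk(cfg$low_threshold > 0 && cfg$high_threshold > cfg$low_threshold,
      "need 0 < low_threshold < high_threshold")
  if (!is.null(effect_genes)) {
    chk(is.data.frame(effect_genes) &&
          all(c("gene", "beta") %in% names(effect_genes)),
        "effect_genes must be a data.frame with columns gene, beta")
    if (is.data.frame(effect_genes) && is.numeric(effect_genes$gene)) {
      chk(all(effect_genes$gene >= 1 & effect_genes$gene <= cfg$n_genes),
          "effect gene index out of range")
    }
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a pharmacogenomic cohort with known ground truth
#'
#' Genotypes: per SNP, a minor-allele frequency is drawn uniformly from
#' `maf_range` and two haplotypes per patient are drawn under
#' Hardy-Weinberg equilibrium. Within a gene, each successive SNP copies
#' the previous SNP's allele on the same haplotype with probability
#' `ld_rho`, inducing local LD; genes are independent. Genes are laid out
#' on disjoint 100-kbp intervals, ten per synthetic chromosome, with SNPs
#' evenly spaced inside the gene body.
#'
#' Phenotype: `dose = baseline + sum_over_effect_genes beta * (minor
#' allele count in gene) + N(0, noise_sd)`, floored at 0.5 mg/day to keep
#' doses physically plausible. Effects act through minor-allele burden —
#' not through the pHap score itself — so detection by the score is a
#' genuine test rather than a circular one.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `genotypes` ([genotype_matrix()]),
#'   `genes` (`gene_intervals`), `phenotypes` (data.frame `sample_id`,
#'   `dose`), `candidate_genes` (character), `truth` (data.frame per
#'   effect gene: `symbol`, `beta`, `var_explained`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  G <- config$n_genes
  gene_syms <- sprintf("GENE%03d", seq_len(G))
  # layout: 10 genes per synthetic chromosome, one 100 kbp slot each
  slot <- (seq_len(G) - 1L) %% 10L
  chrom <- paste0("chrS", (seq_len(G) - 1L) %/% 10L + 1L)
  gstart <- slot * 100000L + 20000L
  gend <- gstart + 60000L
  genes <- structure(data.frame(symbol = gene_syms, chrom = chrom,
                                start = gstart, end = gend,
                                stringsAsFactors = FALSE),
                     class = c("gene_intervals", "data.frame"))
  n_snps <- sample(seq(config$snps_per_gene[1], config$snps_per_gene[2]),
                   G, replace = TRUE)
  dos_cols <- list(); var_rows <- list()
  burden <- matrix(0L, nrow = n, ncol = G)
  for (g in seq_len(G)) {
    m <- n_snps[g]
    q <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
    for (k in seq_len(m)) {
      fresh1 <- stats::rbinom(n, 1L, q[k])
      fresh2 <- stats::rbinom(n, 1L, q[k])
      if (k == 1L || config$ld_rho == 0) {
        hap1[, k] <- fresh1; hap2[, k] <- fresh2
      } else {
        copy1 <- stats::rbinom(n, 1L, config$ld_rho) == 1L
        copy2 <- stats::rbinom(n, 1L, config$ld_rho) == 1L
        hap1[, k] <- ifelse(copy1, hap1[, k - 1L], fresh1)
        hap2[, k] <- ifelse(copy2, hap2[, k - 1L], fresh2)
      }
    }
    dos <- hap1 + hap2
    burden[, g] <- rowSums(dos)
    pos1 <- gstart[g] + round(seq(1000, 59000, length.out = m)) + 1L # 1-based
    var_rows[[g]] <- data.frame(
      variant_id = sprintf("rs%03d%03d", g, seq_len(m)),
      chrom = chrom[g], pos = as.integer(pos1), ref = "A", alt = "G",
      stringsAsFactors = FALSE)
    dos_cols[[g]] <- dos
  }
  dosages <- do.call(cbind, dos_cols)
  variants <- do.call(rbind, var_rows)
  sample_ids <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(dosages, variants, sample_ids)

  eff <- config$effect_genes
  truth <- data.frame(symbol = character(), beta = numeric(),
                      var_explained = numeric(), stringsAsFactors = FALSE)
  genetic <- numeric(n)
  if (!is.null(eff) && nrow(eff) > 0L) {
    idx <- if (is.numeric(eff$gene)) as.integer(eff$gene)
           else match(as.character(eff$gene), gene_syms)
    if (anyNA(idx)) stop("unknown effect gene symbol")
    for (i in seq_along(idx)) {
      genetic <- genetic + eff$beta[i] * burden[, idx[i]]
    }
  }
  noise <- stats::rnorm(n, 0, config$noise_sd)
  dose <- pmax(config$baseline_dose + genetic + noise, 0.5)
  if (!is.null(eff) && nrow(eff) > 0L) {
    vd <- stats::var(dose)
    truth <- data.frame(
      symbol = gene_syms[idx], beta = eff$beta,
      var_explained = vapply(seq_along(idx), function(i)
        stats::var(eff$beta[i] * burden[, idx[i]]) / vd, numeric(1)),
      stringsAsFactors = FALSE)
  }
  phen <- data.frame(sample_id = sample_ids, dose = dose,
                     stringsAsFactors = FALSE)
  structure(list(genotypes = gm, genes = genes, phenotypes = phen,
                 candidate_genes = gene_syms, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' Effect size for a target share of dose variance
#'
#' Returns the per-minor-allele beta (mg/day) so a planted gene explains
#' roughly `h2` of total dose variance, using the Hardy-Weinberg burden
#' variance `sum 2 q (1 - q)` at the mean MAF of `config$maf_range`:
#' `beta^2 V_g = h2 / (1 - h2) * noise_sd^2`.
#'
#' @param config a [sim_config()].
#' @param h2 target variance share in (0, 1), e.g. 0.3 for the ~30% share
#'   a major warfarin pharmacogene can carry.
#' @param n_snps assumed SNP count of the gene (default: midpoint of
#'   `snps_per_gene`).
#' @return beta in mg/day per minor allele.
#' @export
effect_beta_for_variance <- function(config, h2, n_snps = NULL) {
  stopifnot(inherits(config, "sim_config"), h2 > 0, h2 < 1)
  if (is.null(n_snps)) n_snps <- mean(config$snps_per_gene)
  qbar <- mean(config$maf_range)
  v_g <- n_snps * 2 * qbar * (1 - qbar)
  sqrt(h2 / (1 - h2) * config$noise_sd^2 / v_g)
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits the exact files [read_dosage_table()], [read_gene_intervals()],
#' [read_phenotypes()] and [read_gene_list()] consume, plus a truth TSV,
#' and optionally a VCF. Byte-identical for identical cohorts.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @param vcf also write `genotypes.vcf` (default FALSE).
#' @return named character vector of the files written.
#' @export
write_cohort <- function(sim, dir, vcf = FALSE) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             variants = file.path(dir, "variants.tsv"),
             genes = file.path(dir, "genes.bed"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             gene_list = file.path(dir, "candidate_genes.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_dosage_table(sim$genotypes, paths["dosages"], paths["variants"])
  bed <- sim$genes[, c("chrom", "start", "end", "symbol")]
  utils::write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_id = sim$phenotypes$sample_id,
               dose_mg_per_day = sprintf("%.6f", sim$phenotypes$dose)),
    paths["phenotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$candidate_genes, paths["gene_list"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (vcf) {
    paths <- c(paths, vcf = file.path(dir, "genotypes.vcf"))
    write_vcf(sim$genotypes, paths["vcf"])
  }
  paths
}

#' Write a genotype matrix as a minimal VCF
#'
#' GT-only VCF 4.2 with unphased diploid calls; missing dosages become
#' `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  v <- gm$variants
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    d <- gm$dosages[, j]
    gts <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", ".", ".", "GT", gts), collapse = "\t"),
               con)
  }
  invisible(path)
}
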