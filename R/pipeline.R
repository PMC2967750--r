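#' Build and validate a pipeline run configuration
#'
#' All analysis defaults are the method's canonical parameters: r²
#' ceiling 0.2, ±5 kbp gene window, family-wise alpha 0.05, extreme-dose
#' cutoffs 3 and 7 mg/day, 10 cross-validation folds, 100 null
#' replicates. Every parameter is echoed into the run manifest.
#'
#' @param genotypes path to a dosage TSV or VCF (`.vcf`).
#' @param genes path to the BED4 gene annotation.
#' @param phenotypes path to the phenotype TSV.
#' @param gene_list path to the candidate-gene list.
#' @param out_dir output directory for all stage outputs.
#' @param variant_meta optional variant metadata TSV (dosage input only).
#' @param overrides optional SNP-to-gene override TSV.
#' @param freq_mode `"genotype"` or `"allele"`.
#' @param max_r2,window_bp,alpha,low_threshold,high_threshold,folds,null_reps,seed
#'   analysis parameters (see Description for defaults).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genotypes, genes, phenotypes, gene_list, out_dir,
                       variant_meta = NULL, overrides = NULL,
                       freq_mode = c("genotype", "allele"), max_r2 = 0.2,
                       window_bp = 5000, alpha = 0.05, low_threshold = 3,
                       high_threshold = 7, folds = 10L, null_reps = 100L,
                       seed = 1L) {
  freq_mode <- match.arg(freq_mode)
  cfg <- list(genotypes = genotypes, genes = genes, phenotypes = phenotypes,
              gene_list = gene_list, out_dir = out_dir,
              variant_meta = variant_meta, overrides = overrides,
              freq_mode = freq_mode, max_r2 = max_r2,
              window_bp = window_bp, alpha = alpha,
              low_threshold = low_threshold,
              high_threshold = high_threshold, folds = as.integer(folds),
              null_reps = as.integer(null_reps), seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  for (f in c("genotypes", "genes", "phenotypes", "gene_list")) {
    chk(is.character(cfg[[f]]) && file.exists(cfg[[f]]),
        paste0(f, ": file not found (", cfg[[f]], ")"))
  }
  chk(cfg$max_r2 >= 0 && cfg$max_r2 <= 1, "max_r2 must be in [0, 1]")
  chk(cfg$window_bp >= 0, "window_bp must be >= 0")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$low_threshold > 0 && cfg$high_threshold > cfg$low_threshold,
      "need 0 < low_threshold < high_threshold")
  chk(cfg$folds >= 2, "folds must be >= 2")
  chk(cfg$null_reps >= 0, "null_reps must be >= 0")
  if (length(problems)) {
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory. Extra keys are an error.
#'
#' @param path path to the YAML config.
#' @param ... overrides applied on top of the file's values (the CLI
#'   flag-beats-config rule).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  dots <- list(...)
  vals[names(dots)] <- dots
  base <- dirname(normalizePath(path))
  for (f in c("genotypes", "genes", "phenotypes", "gene_list",
              "variant_meta", "overrides")) {
    if (!is.null(vals[[f]]) && !grepl("^/", vals[[f]])) {
      vals[[f]] <- file.path(base, vals[[f]])
    }
  }
  do.call(run_config, vals)
}

#' Run the full gene-score pipeline
#'
#' Executes the method end to end: read and validate inputs, restrict the
#' annotation to the knowledge-filtered candidate list, LD-prune the
#' variants (r² ceiling), map surviving SNPs to genes (±window, manual
#' overrides), estimate frequencies and compute the pHap gene-score
#' matrix, run the per-SNP and per-gene dose regressions, dichotomize at
#' the low/high cutoffs and t-test every gene, and train/evaluate
#' cross-validated logistic classifiers on the strict and nominal feature
#' sets for each extreme (with random-gene-set empirical p-values when
#' `null_reps > 0`). Every stage output is persisted as TSV under
#' `out_dir`, and `manifest.json` records parameters, per-stage counts,
#' correction sizes `m`, seeds and package version. Re-running with an
#' identical config reproduces every output byte for byte.
#'
#' @param config a `run_config` (or path handled by [read_run_config()]).
#' @return (invisibly) list with all in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    writeLines(paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...), log_con)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs in ", config$out_dir, ")", call. = FALSE)
    })
  }
  manifest <- list(parameters = unclass(config),
                   package_version = as.character(utils::packageVersion("phapscore")),
                   stages = list())

  # 1. input
  gm <- stage("input", {
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", config$genotypes)) {
      read_vcf(config$genotypes)
    } else {
      read_dosage_table(config$genotypes, config$variant_meta)
    }
  })
  genes_all <- stage("input", read_gene_intervals(config$genes))
  candidates <- stage("input", read_gene_list(config$gene_list, genes_all))
  phen <- stage("input", read_phenotypes(config$phenotypes, gm))
  overrides <- if (!is.null(config$overrides)) {
    stage("input", read_overrides(config$overrides))
  } else NULL
  genes <- genes_all[genes_all$symbol %in% candidates, ]
  logmsg("input: ", length(gm$sample_ids), " samples, ",
         nrow(gm$variants), " variants, ", nrow(genes_all),
         " annotated genes, ", nrow(genes), " after knowledge filter")
  manifest$stages$input <- list(n_samples = length(gm$sample_ids),
                                n_variants = nrow(gm$variants),
                                n_genes_annotation = nrow(genes_all),
                                n_genes_candidate = nrow(genes))

  # 2. LD pruning
  pr <- stage("prune", ld_prune(gm, config$max_r2))
  gm_kept <- subset_variants(gm, pr$kept_variant_ids)
  writeLines(pr$kept_variant_ids,
             file.path(config$out_dir, "kept_variants.txt"))
  utils::write.table(pr$dropped, file.path(config$out_dir, "drop_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("prune: kept ", length(pr$kept_variant_ids), " of ",
         nrow(gm$variants), " variants at max r2 ", config$max_r2)
  manifest$stages$prune <- list(n_kept = length(pr$kept_variant_ids),
                                n_dropped = nrow(pr$dropped),
                                max_r2 = config$max_r2)

  # 3. SNP -> gene mapping
  map <- stage("map", assign_snps(gm_kept$variants, genes,
                                  window_bp = config$window_bp,
                                  overrides = overrides))
  write_snp_gene_map(map, file.path(config$out_dir, "snp_gene_map.tsv"))
  logmsg("map: ", nrow(map$assignments), " assignments, ",
         length(map$gene_variants), " genes retained")
  manifest$stages$map <- list(n_assignments = nrow(map$assignments),
                              n_genes_mapped = length(map$gene_variants),
                              window_bp = config$window_bp)

  # 4. frequencies + gene scores
  freqs <- stage("score", estimate_frequencies(gm_kept))
  utils::write.table(format(as.data.frame(freqs), digits = 15, trim = TRUE),
                     file.path(config$out_dir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gsm <- stage("score", score_matrix(gm_kept, map, freqs,
                                     mode = config$freq_mode))
  write_gene_scores(gsm, file.path(config$out_dir, "gene_scores.tsv"))
  logmsg("score: ", ncol(gsm$scores), " gene scores per patient (",
         config$freq_mode, " mode)")
  manifest$stages$score <- list(n_gene_scores = ncol(gsm$scores),
                                freq_mode = config$freq_mode)

  # 5. association screens
  snp_assoc <- stage("assoc", run_snp_association(gm_kept, phen,
                                                  alpha = config$alpha))
  write_association_table(snp_assoc,
                          file.path(config$out_dir, "snp_association.tsv"))
  gene_assoc <- stage("assoc", run_gene_association(gsm, phen,
                                                    alpha = config$alpha))
  write_association_table(gene_assoc,
                          file.path(config$out_dir, "gene_association.tsv"))
  logmsg("assoc: m_snp=", attr(snp_assoc, "m"), " m_gene=",
         attr(gene_assoc, "m"))
  manifest$stages$assoc <- list(m_snp = attr(snp_assoc, "m"),
                                m_gene = attr(gene_assoc, "m"),
                                snp_threshold = attr(snp_assoc, "threshold"),
                                gene_threshold = attr(gene_assoc, "threshold"))

  # 6. extreme-dose feature discovery
  manifest$stages$extremes <- list()
  discoveries <- list()
  for (side in c("low", "high")) {
    thr <- if (side == "low") config$low_threshold else config$high_threshold
    labels <- stage("extremes", dichotomize(phen, thr, side))
    disc <- stage("extremes", discover_features(gsm, labels,
                                                alpha = config$alpha))
    utils::write.table(format(disc$table, digits = 15, trim = TRUE),
                       file.path(config$out_dir,
                                 paste0("ttest_", side, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    discoveries[[side]] <- list(labels = labels, discovery = disc)
    logmsg("extremes(", side, "): ", sum(labels$positive), " positives; ",
           length(disc$strict_set), " strict / ",
           length(disc$nominal_set), " nominal features")
    manifest$stages$extremes[[side]] <-
      list(threshold_mg_per_day = thr, n_positive = sum(labels$positive),
           m = attr(disc, "m"), bonferroni_threshold = attr(disc, "threshold"),
           strict = disc$strict_set, nominal = disc$nominal_set)
  }

  # 7. classification
  manifest$stages$classify <- list()
  evals <- list()
  for (side in c("low", "high")) {
    disc <- discoveries[[side]]$discovery
    labels <- discoveries[[side]]$labels
    for (fs in c("strict", "nominal")) {
      feats <- if (fs == "strict") disc$strict_set else disc$nominal_set
      key <- paste0(side, "_", fs)
      if (length(feats) == 0L) {
        logmsg("classify(", key, "): no features, skipped")
        manifest$stages$classify[[key]] <- list(skipped = "no features")
        next
      }
      ev <- stage("classify",
                  evaluate_classifier(gsm, labels, feats, k = config$folds,
                                      seed = config$seed,
                                      null_reps = config$null_reps))
      utils::write.table(
        data.frame(fpr = sprintf("%.10f", ev$roc_points$fpr),
                   tpr = sprintf("%.10f", ev$roc_points$tpr)),
        file.path(config$out_dir, paste0("roc_", key, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      evals[[key]] <- ev
      logmsg("classify(", key, "): AUROC ", format(ev$auroc, digits = 4),
             if (!is.na(ev$empirical_p))
               paste0(", empirical p ", format(ev$empirical_p, digits = 4))
             else "")
      manifest$stages$classify[[key]] <-
        list(features = feats, auroc = ev$auroc,
             empirical_p = ev$empirical_p, folds = config$folds,
             null_reps = config$null_reps, seed = config$seed)
    }
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logmsg("pipeline complete: 7 stages")
  invisible(list(genotypes = gm_kept, prune = pr, map = map, freqs = freqs,
                 gene_scores = gsm, snp_association = snp_assoc,
                 gene_association = gene_assoc, extremes = discoveries,
                 classifiers = evals, manifest = manifest))
}
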