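#' Estimate per-variant genotype and allele frequencies
#'
#' Frequencies are estimated in-cohort over the non-missing calls of each
#' variant: genotype frequency = count of that code / non-missing n;
#' allele frequency = allele count / (2 x non-missing n). No leave-one-out
#' and no pseudocount, so the frequency of any observed genotype is at
#' least `1 / n_observed` and pHap terms are always finite.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame of class `frequency_table`, one row per variant:
#'   `variant_id`, `n_observed`, `f_geno0`, `f_geno1`, `f_geno2`,
#'   `f_ref`, `f_alt`.
#' @export
estimate_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L)) {
    stop("variant(s) with zero non-missing calls: ",
         paste(gm$variants$variant_id[n_obs == 0L], collapse = ", "))
  }
  c0 <- colSums(d == 0L, na.rm = TRUE)
  c1 <- colSums(d == 1L, na.rm = TRUE)
  c2 <- colSums(d == 2L, na.rm = TRUE)
  alt <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  out <- data.frame(
    variant_id = gm$variants$variant_id,
    n_observed = as.integer(n_obs),
    f_geno0 = c0 / n_obs, f_geno1 = c1 / n_obs, f_geno2 = c2 / n_obs,
    f_ref = 1 - alt, f_alt = alt,
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$variant_id
  structure(out, class = c("frequency_table", "data.frame"))
}

#' pHap score of one patient for one gene
#'
#' The pHap statistic: for each of the gene's SNPs, take the negative
#' natural log of the frequency of the patient's observed genotype, then
#' sum over the gene's SNPs. High values mean the patient carries uncommon
#' genotypes in that gene. In `"allele"` mode each of the patient's two
#' allele copies contributes `-log(allele frequency)` instead.
#'
#' Missing genotypes contribute 0 to the sum; the number skipped is
#' returned so the effect is auditable. The log base is natural (nats);
#' any other base only rescales scores and cannot change downstream
#' regression, t-test or classifier results.
#'
#' @param patient_dosages named (or positionally matching) dosage codes
#'   for the variants in `variant_ids`.
#' @param freqs a `frequency_table` from [estimate_frequencies()].
#' @param variant_ids the gene's variant set (non-empty).
#' @param mode `"genotype"` (default) or `"allele"`.
#' @param freq_floor optional lower clamp applied to externally supplied
#'   frequencies; `NULL` (default) means off. A zero frequency with the
#'   floor off is an error.
#' @return list with `score` (>= 0, nats) and `n_missing`.
#' @export
phap_score <- function(patient_dosages, freqs, variant_ids,
                       mode = c("genotype", "allele"), freq_floor = NULL) {
  mode <- match.arg(mode)
  if (length(variant_ids) == 0L) stop("variant set is empty")
  m <- match(variant_ids, freqs$variant_id)
  if (anyNA(m)) {
    stop("variant(s) absent from frequency table: ",
         paste(variant_ids[is.na(m)], collapse = ", "))
  }
  if (!is.null(names(patient_dosages))) {
    patient_dosages <- patient_dosages[variant_ids]
  }
  stopifnot(length(patient_dosages) == length(variant_ids))
  miss <- is.na(patient_dosages)
  if (all(miss)) return(list(score = 0, n_missing = sum(miss)))
  fm <- freqs[m, , drop = FALSE]
  if (mode == "genotype") {
    fcols <- cbind(fm$f_geno0, fm$f_geno1, fm$f_geno2)
    f <- fcols[cbind(seq_along(variant_ids), patient_dosages + 1L)]
    f <- f[!miss]
  } else {
    # two allele copies per call: dosage d -> d alt copies, 2-d ref copies
    d <- patient_dosages[!miss]
    fa <- fm$f_alt[!miss]; fr <- fm$f_ref[!miss]
    # mask zero-multiplicity terms so 0 * log(0) cannot arise
    fa <- ifelse(d == 0, 1, fa)
    fr <- ifelse(d == 2, 1, fr)
    lf <- d * log_floor(fa, freq_floor) + (2 - d) * log_floor(fr, freq_floor)
    return(list(score = -sum(lf), n_missing = sum(miss)))
  }
  list(score = -sum(log_floor(f, freq_floor)), n_missing = sum(miss))
}

# log with optional frequency floor; zero frequency without a floor is an
# error because it can only arise from externally supplied frequencies
log_floor <- function(f, freq_floor) {
  if (!is.null(freq_floor)) f <- pmax(f, freq_floor)
  if (any(f <= 0)) {
    stop("zero frequency for an observed genotype; supply freq_floor when ",
         "using external frequencies")
  }
  log(f)
}

#' Compute the gene-score matrix (patients x genes)
#'
#' One pHap score per (patient, gene in the map). A SNP assigned to
#' several genes contributes its term to each of them.
#'
#' @param gm a [genotype_matrix()].
#' @param map a `snp_gene_map` from [assign_snps()].
#' @param freqs a `frequency_table`; defaults to in-cohort estimates from
#'   `gm`.
#' @param mode `"genotype"` (default) or `"allele"`.
#' @param freq_floor see [phap_score()].
#' @return object of class `gene_score_matrix`: list with `scores`
#'   (numeric matrix, samples x genes, nats), `n_missing` (integer matrix
#'   of skipped calls per score), `mode`, `sample_ids`, `gene_symbols`.
#' @export
score_matrix <- function(gm, map, freqs = NULL,
                         mode = c("genotype", "allele"), freq_floor = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"), inherits(map, "snp_gene_map"))
  if (length(map$gene_variants) == 0L) stop("empty SNP-gene map")
  if (is.null(freqs)) freqs <- estimate_frequencies(gm)
  genes <- names(map$gene_variants)
  scores <- matrix(0, nrow = length(gm$sample_ids), ncol = length(genes),
                   dimnames = list(gm$sample_ids, genes))
  n_missing <- matrix(0L, nrow = nrow(scores), ncol = ncol(scores),
                      dimnames = dimnames(scores))
  # vectorized per gene: look up each patient's genotype (or allele)
  # frequency for every contributing SNP at once, then row-sum the
  # negative logs; missing calls contribute 0
  for (g in seq_along(genes)) {
    vids <- map$gene_variants[[g]]
    sub <- gm$dosages[, vids, drop = FALSE]
    m <- match(vids, freqs$variant_id)
    if (anyNA(m)) {
      stop("variant(s) absent from frequency table: ",
           paste(vids[is.na(m)], collapse = ", "))
    }
    fm <- freqs[m, , drop = FALSE]
    miss <- is.na(sub)
    if (mode == "genotype") {
      fcols <- cbind(fm$f_geno0, fm$f_geno1, fm$f_geno2)
      idx_var <- rep(seq_along(vids), each = nrow(sub))
      f <- matrix(fcols[cbind(idx_var, as.vector(sub) + 1L)],
                  nrow = nrow(sub))
      lf <- -log_floor(ifelse(miss, 1, f), freq_floor)
    } else {
      fa <- matrix(rep(fm$f_alt, each = nrow(sub)), nrow = nrow(sub))
      fr <- matrix(rep(fm$f_ref, each = nrow(sub)), nrow = nrow(sub))
      d <- ifelse(miss, 0, sub)
      # terms with zero multiplicity are masked so an unobserved allele's
      # zero frequency cannot poison the product 0 * log(0)
      fa_safe <- ifelse(miss | d == 0, 1, fa)
      fr_safe <- ifelse(miss | d == 2, 1, fr)
      lf <- -(d * log_floor(fa_safe, freq_floor) +
                (2 - d) * log_floor(fr_safe, freq_floor))
      lf[miss] <- 0
    }
    scores[, g] <- rowSums(lf)
    n_missing[, g] <- rowSums(miss)
  }
  structure(list(scores = scores, n_missing = n_missing, mode = mode,
                 sample_ids = gm$sample_ids, gene_symbols = genes),
            class = "gene_score_matrix")
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat("gene_score_matrix:", nrow(x$scores), "samples x", ncol(x$scores),
      "genes (", x$mode, "frequencies, nats )\n")
  invisible(x)
}

#' Write a gene-score matrix as TSV
#'
#' Rows = samples, columns = genes; first column `sample_id`. The
#' frequency mode used is recorded in a header comment.
#'
#' @param gsm a `gene_score_matrix`.
#' @param path output TSV path.
#' @export
write_gene_scores <- function(gsm, path) {
  stopifnot(inherits(gsm, "gene_score_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# freq_mode=", gsm$mode), con)
  out <- data.frame(sample_id = gsm$sample_ids, gsm$scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(out, digits = 15, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
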