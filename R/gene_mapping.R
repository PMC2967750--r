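#' Assign SNPs to genes within a flanking window
#'
#' A variant is assigned to a gene when its chromosome matches and its
#' 0-based position falls in `[start - window_bp, end + window_bp)`, where
#' `start`/`end` are the gene's BED (0-based half-open) bounds. VCF
#' positions are converted to 0-based once, here, at the mapping boundary.
#' A variant may map to several genes; each gets a copy. Override entries
#' add their (variant, gene) pair unconditionally, regardless of distance.
#' Genes with zero assigned variants are dropped from the map and from all
#' downstream per-gene analyses.
#'
#' @param variants data.frame of variant records (`variant_id`, `chrom`,
#'   `pos` 1-based), e.g. `gm$variants`.
#' @param genes a `gene_intervals` data.frame ([read_gene_intervals()]),
#'   already restricted to the candidate list.
#' @param window_bp flanking window in base pairs (default 5000).
#' @param overrides optional data.frame (`variant_id`, `gene_symbol`);
#'   naming an unknown gene or variant is an error.
#' @return object of class `snp_gene_map`: list with `assignments`
#'   (data.frame `variant_id`, `gene_symbol`), `gene_variants` (named list
#'   of variant ids in positional order per gene), and `n_j` (named integer
#'   vector of per-gene SNP counts).
#' @export
assign_snps <- function(variants, genes, window_bp = 5000, overrides = NULL) {
  if (!is.numeric(window_bp) || window_bp < 0) stop("window_bp must be >= 0")
  stopifnot(is.data.frame(variants), is.data.frame(genes))
  pos0 <- variants$pos - 1L
  pairs <- list()
  for (g in seq_len(nrow(genes))) {
    lo <- genes$start[g] - window_bp
    hi <- genes$end[g] + window_bp          # half-open upper bound
    hit <- variants$chrom == genes$chrom[g] & pos0 >= lo & pos0 < hi
    if (any(hit)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        variant_id = variants$variant_id[hit],
        gene_symbol = genes$symbol[g], stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(variant_id = character(), gene_symbol = character(),
               stringsAsFactors = FALSE)
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    unknown_g <- setdiff(overrides$gene_symbol, genes$symbol)
    if (length(unknown_g)) {
      stop("override names unknown gene(s): ", paste(unknown_g, collapse = ", "))
    }
    unknown_v <- setdiff(overrides$variant_id, variants$variant_id)
    if (length(unknown_v)) {
      stop("override names unknown variant(s): ", paste(unknown_v, collapse = ", "))
    }
    assignments <- rbind(assignments,
                         overrides[, c("variant_id", "gene_symbol")])
  }
  assignments <- unique(assignments)
  if (nrow(assignments) == 0L) stop("no variant maps to any candidate gene")
  # per-gene variant lists in positional order; gene order follows `genes`
  kept_genes <- genes$symbol[genes$symbol %in% assignments$gene_symbol]
  vorder <- order(variants$chrom, variants$pos, variants$variant_id)
  ranked <- variants$variant_id[vorder]
  gene_variants <- lapply(kept_genes, function(sym) {
    ids <- assignments$variant_id[assignments$gene_symbol == sym]
    ranked[ranked %in% ids]
  })
  names(gene_variants) <- kept_genes
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 gene_variants = gene_variants,
                 n_j = vapply(gene_variants, length, integer(1))),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat("snp_gene_map:", nrow(x$assignments), "assignments across",
      length(x$gene_variants), "genes (N_j range",
      min(x$n_j), "-", max(x$n_j), ")\n")
  invisible(x)
}

#' Write a SNP-to-gene map as TSV
#'
#' @param map a `snp_gene_map`.
#' @param path output TSV path (columns `variant_id`, `gene_symbol`).
#' @export
write_snp_gene_map <- function(map, path) {
  stopifnot(inherits(map, "snp_gene_map"))
  utils::write.table(map$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
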