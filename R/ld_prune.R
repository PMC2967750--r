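#' Pairwise r-squared between two dosage vectors
#'
#' Composite-genotype linkage disequilibrium: the squared Pearson
#' correlation of the 0/1/2 dosage vectors, computed over
#' pairwise-complete samples. No phasing or EM haplotype inference is
#' attempted.
#'
#' @param a,b integer dosage vectors of equal length (`NA` = missing).
#' @return r-squared in `[0, 1]`, or `NA_real_` (the "not computable"
#'   sentinel) when fewer than 2 complete pairs remain or either vector is
#'   constant on the complete pairs.
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors differ in length")
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) return(NA_real_)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  r <- stats::cor(a, b)
  min(r * r, 1)
}

#' Prune variants by pairwise linkage disequilibrium
#'
#' Greedy sweep in (chrom, pos, variant_id) order: a variant is kept iff
#' its r-squared with every already-kept variant on the same chromosome is
#' at most `max_r2`. Deterministic for a fixed input. Pairs whose r² is
#' not computable (constant column, too much missingness) are treated as
#' independent (r² = 0).
#'
#' @param gm a [genotype_matrix()].
#' @param max_r2 maximum tolerated pairwise r-squared (default 0.2).
#' @return list of class `prune_result` with elements
#'   `kept_variant_ids` (ordered character vector) and `dropped`
#'   (data.frame: `dropped_id`, `blocking_kept_id`, `r2`).
#' @export
ld_prune <- function(gm, max_r2 = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$variants) == 0L) stop("empty genotype matrix")
  if (!is.numeric(max_r2) || max_r2 < 0 || max_r2 > 1) {
    stop("max_r2 must be in [0, 1]")
  }
  v <- gm$variants
  ord <- order(v$chrom, v$pos, v$variant_id)
  kept_idx <- integer(0)
  dropped <- list()
  for (i in ord) {
    same_chr <- kept_idx[v$chrom[kept_idx] == v$chrom[i]]
    blocked <- FALSE
    for (j in same_chr) {
      r2 <- pairwise_r2(gm$dosages[, i], gm$dosages[, j])
      if (!is.na(r2) && r2 > max_r2) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          dropped_id = v$variant_id[i],
          blocking_kept_id = v$variant_id[j],
          r2 = r2, stringsAsFactors = FALSE)
        blocked <- TRUE
        break
      }
    }
    if (!blocked) kept_idx <- c(kept_idx, i)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(dropped_id = character(), blocking_kept_id = character(),
               r2 = numeric(), stringsAsFactors = FALSE)
  structure(list(kept_variant_ids = v$variant_id[kept_idx],
                 dropped = dropped, max_r2 = max_r2),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result:", length(x$kept_variant_ids), "kept,",
      nrow(x$dropped), "dropped (max r2 =", x$max_r2, ")\n")
  invisible(x)
}

#' Subset a genotype matrix to a set of variants
#'
#' @param gm a [genotype_matrix()].
#' @param variant_ids variant ids to retain, in the order given.
#' @return a [genotype_matrix()] restricted to `variant_ids`.
#' @export
subset_variants <- function(gm, variant_ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- match(variant_ids, gm$variants$variant_id)
  if (anyNA(m)) {
    stop("unknown variant id(s): ",
         paste(variant_ids[is.na(m)], collapse = ", "))
  }
  genotype_matrix(gm$dosages[, m, drop = FALSE], gm$variants[m, ],
                  gm$sample_ids)
}
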