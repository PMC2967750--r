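#' Univariate ordinary least squares with a two-sided slope test
#'
#' Closed-form OLS of `y` on `x` over pairwise-complete observations, with
#' the usual t test on the slope (two-sided, `n - 2` df). A perfect fit
#' (zero residual variance) gets the smallest positive representable
#' p-value and is flagged.
#'
#' @param x predictor vector (non-constant after complete-case filtering).
#' @param y response vector, same length.
#' @return list: `slope`, `intercept`, `t_stat`, `df`, `p_value`,
#'   `n_used`, `perfect_fit`.
#' @export
fit_univariate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero-variance predictor")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  df <- n - 2L
  perfect <- rss <= .Machine$double.eps * sum(y^2) * n
  if (perfect) {
    t_stat <- Inf
    p <- .Machine$double.xmin
  } else {
    se <- sqrt(rss / df / sxx)
    t_stat <- slope / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    p <- max(p, .Machine$double.xmin)
  }
  list(slope = slope, intercept = intercept, t_stat = t_stat, df = df,
       p_value = p, n_used = n, perfect_fit = perfect)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control: each of `m` tests is compared against
#' `alpha / m`.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer")
  alpha / m
}

# shared core of the SNP-level and gene-level screens: one OLS row per
# feature column, Bonferroni over the features actually tested
association_screen <- function(feature_mat, dose, alpha,
                               alpha_corrected_override = NULL) {
  feats <- colnames(feature_mat)
  rows <- vector("list", length(feats))
  skipped <- character(0)
  for (k in seq_along(feats)) {
    xk <- feature_mat[, k]
    ok <- !is.na(xk) & !is.na(dose)
    if (sum(ok) < 3L || stats::var(as.numeric(xk[ok])) == 0) {
      skipped <- c(skipped, feats[k])
      next
    }
    f <- fit_univariate(xk, dose)
    rows[[k]] <- data.frame(feature = feats[k], slope = f$slope,
                            intercept = f$intercept, t_stat = f$t_stat,
                            df = f$df, p_value = f$p_value,
                            n_used = f$n_used, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) stop("no testable feature")
  m <- nrow(tab)
  thr <- if (is.null(alpha_corrected_override)) bonferroni_threshold(alpha, m)
         else alpha_corrected_override
  tab$significant_after_correction <- tab$p_value <= thr
  tab <- tab[order(tab$p_value, tab$feature), ]
  rownames(tab) <- NULL
  structure(tab,
            class = c("association_table", "data.frame"),
            m = m, alpha = alpha, threshold = thr, skipped = skipped)
}

#' Per-SNP univariate regression screen
#'
#' One OLS of stable dose on dosage per SNP, sorted ascending by p-value,
#' Bonferroni-corrected over the SNPs actually tested. Zero-variance
#' dosage columns are skipped (recorded in `attr(, "skipped")`), not
#' crashed on.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotypes phenotype data.frame (`sample_id`, `dose`) as from
#'   [read_phenotypes()]; reconciled to `gm` by id.
#' @param snp_set variant ids to test (default: all in `gm`).
#' @param alpha family-wise error rate (default 0.05).
#' @param alpha_corrected_override optional explicit corrected threshold
#'   replacing `alpha / m`.
#' @return data.frame of class `association_table`, one row per SNP, with
#'   attributes `m`, `alpha`, `threshold`, `skipped`.
#' @export
run_snp_association <- function(gm, phenotypes, snp_set = NULL, alpha = 0.05,
                                alpha_corrected_override = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(snp_set)) snp_set <- gm$variants$variant_id
  if (length(snp_set) == 0L) stop("empty snp_set")
  sub <- subset_variants(gm, snp_set)
  dose <- reconcile_dose(phenotypes, sub$sample_ids)
  association_screen(sub$dosages, dose, alpha, alpha_corrected_override)
}

#' Per-gene-score univariate regression screen
#'
#' One OLS of stable dose on the pHap gene-score per gene; correction uses
#' `m` = number of genes tested.
#'
#' @param gene_scores a `gene_score_matrix` from [score_matrix()].
#' @inheritParams run_snp_association
#' @return data.frame of class `association_table`, one row per gene.
#' @export
run_gene_association <- function(gene_scores, phenotypes, alpha = 0.05,
                                 alpha_corrected_override = NULL) {
  stopifnot(inherits(gene_scores, "gene_score_matrix"))
  dose <- reconcile_dose(phenotypes, gene_scores$sample_ids)
  association_screen(gene_scores$scores, dose, alpha,
                     alpha_corrected_override)
}

# match dose values to a sample-id order; id-based, never positional
reconcile_dose <- function(phenotypes, sample_ids) {
  m <- match(sample_ids, phenotypes$sample_id)
  if (anyNA(m)) {
    stop("samples missing from phenotype table: ",
         paste(sample_ids[is.na(m)], collapse = ", "))
  }
  phenotypes$dose[m]
}

#' Write an association table as TSV
#'
#' The header comment records `m`, `alpha` and the corrected threshold so
#' the multiplicity correction is auditable from the file alone.
#'
#' @param tab an `association_table`.
#' @param path output TSV path.
#' @export
write_association_table <- function(tab, path) {
  stopifnot(inherits(tab, "association_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m=%d alpha=%g threshold=%g", attr(tab, "m"),
                     attr(tab, "alpha"), attr(tab, "threshold")), con)
  utils::write.table(format(as.data.frame(tab), digits = 15, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
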