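#' Dichotomize patients into extreme-dose classes
#'
#' `direction = "low"` labels positive every patient with dose <=
#' `threshold`; `direction = "high"` labels positive every patient with
#' dose >= `threshold`. Both comparisons are inclusive, matching the
#' clinical definitions "low stable dose (<= 3 mg/day)" and "high stable
#' dose (>= 7 mg/day)". An empty class is an error because every
#' downstream test needs both.
#'
#' @param phenotypes data.frame (`sample_id`, `dose`).
#' @param threshold dose threshold in mg/day (> 0).
#' @param direction `"low"` or `"high"`.
#' @return object of class `dose_labels`: data.frame (`sample_id`,
#'   `positive` logical) with attributes `threshold`, `direction`.
#' @export
dichotomize <- function(phenotypes, threshold, direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  pos <- if (direction == "low") phenotypes$dose <= threshold
         else phenotypes$dose >= threshold
  if (!any(pos)) stop("empty positive class at ", direction, " threshold ",
                      threshold, " mg/day")
  if (all(pos)) stop("empty negative class at ", direction, " threshold ",
                     threshold, " mg/day")
  structure(data.frame(sample_id = phenotypes$sample_id, positive = pos,
                       stringsAsFactors = FALSE),
            class = c("dose_labels", "data.frame"),
            threshold = threshold, direction = direction)
}

#' Two-sample Student's t test on gene-score groups
#'
#' Classic pooled-variance Student's t (two-sided, `n1 + n2 - 2` df) by
#' default; `welch = TRUE` switches to the unequal-variance form. Zero
#' pooled variance with equal means yields `t = 0, p = 1`.
#'
#' @param scores_pos,scores_neg score vectors of the two classes, each of
#'   length >= 2.
#' @param welch use the Welch correction instead of pooling.
#' @return list: `t_stat`, `df`, `p_value`, `mean_positive`,
#'   `mean_negative`.
#' @export
gene_ttest <- function(scores_pos, scores_neg, welch = FALSE) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 observations")
  m1 <- mean(scores_pos); m2 <- mean(scores_neg)
  v1 <- stats::var(scores_pos); v2 <- stats::var(scores_neg)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      return(list(t_stat = 0, df = n1 + n2 - 2L, p_value = 1,
                  mean_positive = m1, mean_negative = m2))
    }
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2L
    if (sp2 == 0) {
      if (m1 == m2) {
        return(list(t_stat = 0, df = df, p_value = 1,
                    mean_positive = m1, mean_negative = m2))
      }
      return(list(t_stat = sign(m1 - m2) * Inf, df = df,
                  p_value = .Machine$double.xmin,
                  mean_positive = m1, mean_negative = m2))
    }
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       mean_positive = m1, mean_negative = m2)
}

#' Discover genes whose scores separate extreme-dose classes
#'
#' Runs [gene_ttest()] for every gene in the score matrix against the
#' dichotomized labels. `strict_set` holds genes passing Bonferroni at
#' `alpha` over the genes actually tested; `nominal_set` holds genes with
#' raw p <= 0.05 (always a superset of `strict_set`). Genes with a group
#' smaller than 2 are skipped and recorded.
#'
#' @param gene_scores a `gene_score_matrix`.
#' @param labels a `dose_labels` object; reconciled to the score matrix
#'   by sample id.
#' @param alpha family-wise error rate for the strict set (default 0.05).
#' @param welch see [gene_ttest()].
#' @param alpha_corrected_override optional explicit corrected threshold.
#' @return list of class `feature_discovery`: `strict_set`, `nominal_set`
#'   (character vectors), `table` (data.frame sorted ascending by p with
#'   columns `gene`, `t_stat`, `df`, `p_value`, `mean_positive`,
#'   `mean_negative`, `nominal_significant`,
#'   `significant_after_correction`), plus attributes `m`, `threshold`,
#'   `skipped`.
#' @export
discover_features <- function(gene_scores, labels, alpha = 0.05,
                              welch = FALSE,
                              alpha_corrected_override = NULL) {
  stopifnot(inherits(gene_scores, "gene_score_matrix"),
            inherits(labels, "dose_labels"))
  m_idx <- match(gene_scores$sample_ids, labels$sample_id)
  if (anyNA(m_idx)) {
    stop("samples missing from labels: ",
         paste(gene_scores$sample_ids[is.na(m_idx)], collapse = ", "))
  }
  pos <- labels$positive[m_idx]
  rows <- list(); skipped <- character(0)
  for (g in gene_scores$gene_symbols) {
    sp <- gene_scores$scores[pos, g]
    sn <- gene_scores$scores[!pos, g]
    if (length(sp) < 2L || length(sn) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    tt <- gene_ttest(sp, sn, welch = welch)
    rows[[g]] <- data.frame(gene = g, t_stat = tt$t_stat, df = tt$df,
                            p_value = tt$p_value,
                            mean_positive = tt$mean_positive,
                            mean_negative = tt$mean_negative,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable gene")
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  thr <- if (is.null(alpha_corrected_override)) bonferroni_threshold(alpha, m)
         else alpha_corrected_override
  tab$nominal_significant <- tab$p_value <= 0.05
  tab$significant_after_correction <- tab$p_value <= thr
  tab <- tab[order(tab$p_value, tab$gene), ]
  rownames(tab) <- NULL
  structure(list(strict_set = tab$gene[tab$significant_after_correction],
                 nominal_set = tab$gene[tab$nominal_significant],
                 table = tab),
            class = "feature_discovery",
            m = m, alpha = alpha, threshold = thr, skipped = skipped)
}

#' @export
print.feature_discovery <- function(x, ...) {
  cat("feature_discovery:", length(x$strict_set), "strict /",
      length(x$nominal_set), "nominal of", attr(x, "m"),
      "genes tested (threshold", format(attr(x, "threshold")), ")\n")
  invisible(x)
}
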