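#' Fit a logistic regression classifier
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares, with a small ridge penalty (default 1e-6) on the non-intercept
#' weights. The penalty is numerically irrelevant away from separation but
#' keeps the optimum finite under the quasi-separation that small cohorts
#' with strong features routinely produce; set `ridge = 0` for pure ML.
#'
#' @param features numeric matrix (samples x features).
#' @param labels logical (or 0/1) vector; both classes must have >= 2
#'   members.
#' @param ridge ridge penalty strength on non-intercept weights.
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on the max absolute coefficient step.
#' @return numeric coefficient vector: intercept followed by one weight
#'   per feature column.
#' @export
fit_logistic <- function(features, labels, ridge = 1e-6,
                         max_iter = 100L, tol = 1e-10) {
  X <- cbind(1, as.matrix(features))
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("each class needs >= 2 samples")
  }
  p <- ncol(X)
  pen_diag <- c(0, rep(ridge, p - 1L))
  pen <- diag(pen_diag, nrow = p)
  # penalized deviance: -2 loglik + ridge * sum(w^2)
  pdev <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable softplus: log(1 + exp(eta))
    sp <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    -2 * sum(y * eta - sp) + sum(pen_diag * b^2)
  }
  beta <- numeric(p)
  dev <- pdev(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    # penalized Newton step via weighted normal equations, with
    # step-halving so the penalized deviance never increases
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- tryCatch(drop(solve(H, g)), error = function(e)
      stop("IRLS failed: singular weighted design (possible separation)"))
    beta_new <- beta + step
    dev_new <- pdev(beta_new)
    halvings <- 0L
    while (!is.finite(dev_new) || dev_new > dev + 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      beta_new <- beta + step
      dev_new <- pdev(beta_new)
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    if (abs(dev - dev_new) < tol * (abs(dev_new) + 0.1) &&
        moved < 1e-6 * (1 + max(abs(beta)))) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    # diagnose separation: all fitted probabilities saturated on the
    # correct side means the unpenalized ML optimum is at infinity
    mu <- stats::plogis(drop(X %*% beta))
    sep <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)
    stop("logistic fit did not converge in ", max_iter, " iterations",
         if (sep) " (complete separation detected)" else "")
  }
  names(beta) <- c("(Intercept)", colnames(as.matrix(features)))
  beta
}

#' Predicted class probabilities from a logistic fit
#'
#' @param beta coefficient vector from [fit_logistic()].
#' @param features numeric matrix (samples x features).
#' @return vector of probabilities in (0, 1).
#' @export
predict_logistic <- function(beta, features) {
  stats::plogis(drop(cbind(1, as.matrix(features)) %*% beta))
}

# deterministic stratified fold assignment: shuffle within class, deal
# round-robin so fold sizes are near-equal and every fold sees both
# classes whenever each class has >= k members
make_folds <- function(labels, k, seed) {
  y <- as.logical(labels)
  n <- length(y)
  n_min <- min(sum(y), sum(!y))
  if (n_min < 2L) stop("each class needs >= 2 samples for cross-validation")
  if (k > n_min) {
    warning("k lowered from ", k, " to ", n_min,
            " so every fold can contain both classes")
    k <- n_min
  }
  if (k < 2L) stop("k must be >= 2")
  fold <- integer(n)
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Out-of-fold probabilities from stratified k-fold cross-validation
#'
#' Stratified folds of near-equal size; every sample is scored exactly
#' once, by a model never trained on it. Deterministic given `seed`. If a
#' class has fewer than `k` members, `k` is lowered with a warning.
#'
#' @param features numeric matrix (samples x features).
#' @param labels logical (or 0/1) class vector.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param ridge passed to [fit_logistic()].
#' @return numeric vector of out-of-fold probabilities, one per sample,
#'   with the fold assignment in `attr(, "fold")`.
#' @export
cross_validate <- function(features, labels, k = 10L, seed = 1L,
                           ridge = 1e-6) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  fold <- make_folds(y, k, seed)
  probs <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    beta <- fit_logistic(X[!test, , drop = FALSE], y[!test], ridge = ridge)
    probs[test] <- predict_logistic(beta, X[test, , drop = FALSE])
  }
  attr(probs, "fold") <- fold
  probs
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) pairs in which
#' the positive sample outscores the negative one, ties counted one half.
#' Equal to the trapezoidal area under the ROC curve.
#'
#' @param probs numeric score/probability vector.
#' @param labels logical (or 0/1) class vector; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(probs, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(probs, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sweeps the decision threshold through the distinct scores, from
#' (0, 0) to (1, 1); ties move diagonally, so the trapezoidal area equals
#' [auroc()].
#'
#' @inheritParams auroc
#' @return data.frame with columns `fpr`, `tpr`, monotone non-decreasing
#'   in both.
#' @export
roc_points <- function(probs, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  # group tied scores so ties produce a single diagonal segment
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(tapply(ys, grp, sum))
  fp <- cumsum(tapply(!ys, grp, sum))
  data.frame(fpr = c(0, unname(fp) / n_neg),
             tpr = c(0, unname(tp) / n_pos))
}

#' Empirical significance of a classifier via random gene sets
#'
#' Null model: classifiers trained on gene sets of the same size drawn at
#' random (without replacement within a draw) from the candidate pool,
#' each evaluated with the identical cross-validation procedure. The
#' empirical p-value uses the add-one formula
#' `(1 + #\{null AUROC >= observed\}) / (1 + B)`, so its floor with
#' `B = 100` is 1/101 (just under 0.01) and it is never zero; `>=` is the
#' conservative tie handling.
#'
#' @param observed_auroc AUROC of the classifier under test.
#' @param gene_scores a `gene_score_matrix` providing the gene pool.
#' @param labels a `dose_labels` object (or logical vector aligned to the
#'   score matrix samples).
#' @param n_features number of genes per random draw.
#' @param B number of null replicates (default 100).
#' @param k cross-validation folds (default 10).
#' @param seed RNG seed governing both the draws and each CV split.
#' @param ridge passed to [fit_logistic()].
#' @return list: `empirical_p`, `null_aurocs` (length `B`).
#' @export
empirical_significance <- function(observed_auroc, gene_scores, labels,
                                   n_features, B = 100L, k = 10L,
                                   seed = 1L, ridge = 1e-6) {
  stopifnot(inherits(gene_scores, "gene_score_matrix"))
  if (B < 1L) stop("B must be >= 1")
  pool <- gene_scores$gene_symbols
  if (n_features > length(pool)) {
    stop("gene pool (", length(pool), ") smaller than n_features (",
         n_features, ")")
  }
  y <- label_vector(labels, gene_scores$sample_ids)
  null_aurocs <- numeric(B)
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max, B)
  for (b in seq_len(B)) {
    set.seed(draw_seeds[b])
    genes_b <- sample(pool, n_features)
    Xb <- gene_scores$scores[, genes_b, drop = FALSE]
    pb <- cross_validate(Xb, y, k = k, seed = draw_seeds[b], ridge = ridge)
    null_aurocs[b] <- auroc(pb, y)
  }
  list(empirical_p = (1 + sum(null_aurocs >= observed_auroc)) / (1 + B),
       null_aurocs = null_aurocs)
}

# accept either a dose_labels object or a plain logical vector
label_vector <- function(labels, sample_ids) {
  if (inherits(labels, "dose_labels")) {
    m <- match(sample_ids, labels$sample_id)
    if (anyNA(m)) stop("samples missing from labels")
    labels$positive[m]
  } else {
    stopifnot(length(labels) == length(sample_ids))
    as.logical(labels)
  }
}

#' Cross-validated evaluation of a gene-score classifier
#'
#' Convenience wrapper: selects the feature genes from the score matrix,
#' runs stratified k-fold cross-validation, pools the out-of-fold
#' probabilities into one ROC curve and AUROC, and (optionally) computes
#' the random-gene-set empirical p-value.
#'
#' @param gene_scores a `gene_score_matrix`.
#' @param labels a `dose_labels` object or logical vector.
#' @param feature_genes character vector of gene symbols to use as
#'   features.
#' @param k folds (default 10).
#' @param seed RNG seed.
#' @param null_reps `B` for [empirical_significance()]; 0 skips it.
#' @param ridge passed to [fit_logistic()].
#' @return object of class `classifier_eval`: list with `feature_genes`,
#'   `out_of_fold_probs`, `roc_points`, `auroc`, `cv_seed`, `empirical_p`
#'   (NA when `null_reps = 0`), `null_aurocs`.
#' @export
evaluate_classifier <- function(gene_scores, labels, feature_genes,
                                k = 10L, seed = 1L, null_reps = 100L,
                                ridge = 1e-6) {
  stopifnot(inherits(gene_scores, "gene_score_matrix"))
  missing_g <- setdiff(feature_genes, gene_scores$gene_symbols)
  if (length(missing_g)) {
    stop("feature gene(s) absent from score matrix: ",
         paste(missing_g, collapse = ", "))
  }
  y <- label_vector(labels, gene_scores$sample_ids)
  X <- gene_scores$scores[, feature_genes, drop = FALSE]
  probs <- cross_validate(X, y, k = k, seed = seed, ridge = ridge)
  a <- auroc(probs, y)
  emp <- list(empirical_p = NA_real_, null_aurocs = numeric(0))
  if (null_reps > 0L) {
    emp <- empirical_significance(a, gene_scores, y,
                                  n_features = length(feature_genes),
                                  B = null_reps, k = k, seed = seed + 1L,
                                  ridge = ridge)
  }
  structure(list(feature_genes = feature_genes,
                 out_of_fold_probs = as.numeric(probs),
                 fold = attr(probs, "fold"),
                 roc_points = roc_points(probs, y),
                 auroc = a, cv_seed = seed,
                 empirical_p = emp$empirical_p,
                 null_aurocs = emp$null_aurocs),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat("classifier_eval:", length(x$feature_genes), "feature genes; AUROC",
      format(x$auroc, digits = 4),
      if (!is.na(x$empirical_p))
        paste0("; empirical p ", format(x$empirical_p, digits = 4)) else "",
      "\n", sep = "")
  invisible(x)
}
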