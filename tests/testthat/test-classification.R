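sep_data <- function(n = 40, gap = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n) + ifelse(y, gap, 0), ncol = 1)
  colnames(x) <- "f1"
  list(x = x, y = y)
}

test_that("fit_logistic matches the glm oracle at ridge = 0", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 80
    X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(n, 1, stats::plogis(0.5 * X[, 1] - X[, 2]))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    beta <- fit_logistic(X, y, ridge = 0)
    o <- stats::glm(y ~ X, family = stats::binomial())
    expect_equal(unname(beta), unname(stats::coef(o)), tolerance = 1e-6)
  }
})

test_that("null features get near-zero weights; separable data order exactly", {
  # |w| < 0.1 is a ~2 SE statement at n = 2000 (SE ~ 1/sqrt(0.25 n))
  set.seed(10)
  X <- matrix(rnorm(2000), ncol = 1)
  y <- rep(c(0, 1), 1000)
  beta <- fit_logistic(X, y)
  expect_lt(abs(beta[2]), 0.1)
  expect_lt(abs(beta[1]), 0.1)

  d <- sep_data()
  beta_s <- fit_logistic(d$x, d$y)
  p <- predict_logistic(beta_s, d$x)
  expect_equal(order(p), order(d$x[, 1]))  # monotone link
  expect_error(fit_logistic(d$x, rep(1, 40)), ">= 2")
})

test_that("cross_validate partitions samples into stratified folds", {
  d <- sep_data(n = 20, gap = 3)
  probs <- cross_validate(d$x, d$y, k = 10, seed = 4)
  fold <- attr(probs, "fold")
  expect_equal(as.integer(table(fold)), rep(2L, 10))  # n=20, k=10: 2 per fold
  expect_true(all(!is.na(probs)))
  # stratified: every fold has one of each class
  expect_true(all(tapply(d$y, fold, sum) == 1))
  # deterministic given seed
  expect_identical(as.numeric(probs),
                   as.numeric(cross_validate(d$x, d$y, k = 10, seed = 4)))
  # leave-one-out at k = n works per class
  loo <- cross_validate(d$x, d$y, k = 10, seed = 9)
  expect_length(loo, 20)
})

test_that("k is lowered with a warning when a class is small", {
  set.seed(5)
  y <- c(rep(TRUE, 4), rep(FALSE, 30))
  x <- matrix(rnorm(34) + y, ncol = 1)
  expect_warning(probs <- cross_validate(x, y, k = 10, seed = 2),
                 "lowered")
  expect_true(all(!is.na(probs)))
})

test_that("well-separated classes give high out-of-fold AUROC", {
  d <- sep_data(n = 60, gap = 3, seed = 6)  # ~3 pooled SDs apart
  probs <- cross_validate(d$x, d$y, k = 10, seed = 3)
  expect_gt(auroc(probs, d$y), 0.95)
})

test_that("auroc equals the tie-aware pair fraction", {
  expect_equal(auroc(c(0.9, 0.7, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  # enumerated: pairs (1,1,0.5,1)/4
  expect_equal(auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(auroc(c(0.2, 0.4), c(1, 1)), "both classes")

  # random cases vs brute-force pair enumeration
  for (seed in 1:6) {
    set.seed(seed)
    n <- 30
    y <- rbinom(n, 1, 0.4) == 1
    if (!any(y) || all(y)) next
    p <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # plenty of ties
    pairs <- 0; wins <- 0
    for (i in which(y)) for (j in which(!y)) {
      pairs <- pairs + 1
      wins <- wins + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
    }
    expect_equal(auroc(p, y), wins / pairs, tolerance = 1e-12)
  }
})

test_that("auroc complements on label flip and is monotone-invariant", {
  set.seed(8)
  y <- rbinom(40, 1, 0.5) == 1
  p <- runif(40)
  expect_equal(auroc(p, y) + auroc(p, !y), 1.0, tolerance = 1e-12)
  expect_equal(auroc(stats::qlogis(p * 0.98 + 0.01), y), auroc(p, y),
               tolerance = 1e-12)
})

test_that("roc_points span (0,0) to (1,1), are monotone, and integrate to auroc", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- c(TRUE, FALSE, rbinom(28, 1, 0.5) == 1)
    p <- sample(seq(0, 1, 0.2), 30, replace = TRUE)
    roc <- roc_points(p, y)
    expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                   utils::tail(roc$tpr, -1)) / 2)
    expect_equal(trap, auroc(p, y), tolerance = 1e-12)
  }
})

test_that("empirical p has floor 1/(B+1) and ceiling 1", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_genes = 8, seed = 71))
  gsm <- score_cohort(sim)
  labels <- dichotomize(sim$phenotypes, stats::median(sim$phenotypes$dose),
                        "low")
  emp_hi <- empirical_significance(2, gsm, labels, n_features = 2, B = 25,
                                   k = 5, seed = 3)
  expect_equal(emp_hi$empirical_p, 1 / 26)  # observed above every null
  emp_lo <- empirical_significance(-1, gsm, labels, n_features = 2, B = 25,
                                   k = 5, seed = 3)
  expect_equal(emp_lo$empirical_p, 1.0)
  expect_length(emp_hi$null_aurocs, 25)
  expect_error(empirical_significance(0.5, gsm, labels, n_features = 99,
                                      B = 5, k = 5, seed = 1), "pool")
})

test_that("evaluate_classifier ties the pieces together deterministically", {
  sim <- simulate_cohort(sim_config(n_samples = 60, n_genes = 10, seed = 81))
  gsm <- score_cohort(sim)
  labels <- dichotomize(sim$phenotypes, stats::median(sim$phenotypes$dose),
                        "low")
  ev <- evaluate_classifier(gsm, labels, c("GENE001", "GENE002"), k = 5,
                            seed = 2, null_reps = 10)
  expect_equal(ev$auroc, auroc(ev$out_of_fold_probs,
                               label_vec <- labels$positive))
  expect_gte(ev$empirical_p, 1 / 11)
  ev2 <- evaluate_classifier(gsm, labels, c("GENE001", "GENE002"), k = 5,
                             seed = 2, null_reps = 10)
  expect_identical(ev$out_of_fold_probs, ev2$out_of_fold_probs)
  expect_identical(ev$empirical_p, ev2$empirical_p)
  expect_error(evaluate_classifier(gsm, labels, "NOSUCH"), "absent")
})

test_that("planted separating genes beat the random-gene null (scaled down)", {
  # scaled from the full 20-replicate / B=100 design to fit the test
  # budget: 6 replicates, B = 30; the add-one floor is then 1/31
  wins <- 0
  for (r in 1:6) {
    sim <- simulate_cohort(sim_config(n_samples = 100, n_genes = 20,
                                      seed = 900 + r))
    gsm <- score_cohort(sim)
    labels <- dichotomize(sim$phenotypes,
                          stats::median(sim$phenotypes$dose), "low")
    for (g in c("GENE003", "GENE007")) {
      gsm$scores[labels$positive, g] <-
        gsm$scores[labels$positive, g] + 3 * stats::sd(gsm$scores[, g])
    }
    disc <- discover_features(gsm, labels)
    feats <- unique(c("GENE003", "GENE007", disc$strict_set))
    ev <- evaluate_classifier(gsm, labels, feats, k = 10, seed = r,
                              null_reps = 30)
    wins <- wins + (ev$empirical_p == 1 / 31)
  }
  expect_gte(wins, 5)
})
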