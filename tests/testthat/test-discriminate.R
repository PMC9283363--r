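make_logistic_data <- function(n = 200, p = 10, seed = 1, beta = NULL,
                               intercept = 0.2) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("x", seq_len(p))
  beta <- beta %||% c(1, -0.5, rep(0, p - 2))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y)
}

test_that("with no penalty and no random effect the fit equals independent IRLS", {
  for (seed in 1:5) {
    d <- make_logistic_data(n = 200, p = 10, seed = seed)
    fit <- fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 0.1, lambda = 0,
                          tol = 1e-8)
    oracle <- oracle_irls_logistic(d$X, d$y)
    expect_lt(max(abs(coef(fit) - oracle)), 1e-4)
  }
})

test_that("penalised fits match glmnet at matching parameterisation", {
  skip_if_not_installed("glmnet")
  d <- make_logistic_data(n = 250, p = 8, seed = 7)
  for (lam in c(1e-4, 0.02, 0.08)) {
    fit <- fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 0.1, lambda = lam,
                          tol = 1e-9, inner_tol = 1e-9)
    gn <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.1,
                         lambda = lam, standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(c(fit$beta0 - gn$a0,
                        fit$beta - as.numeric(gn$beta)))), 1e-5)
  }
})

test_that("a huge penalty shrinks all penalised coefficients to exactly zero", {
  d <- make_logistic_data(seed = 8)
  fit <- fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 0.5, lambda = 50)
  expect_true(all(fit$beta == 0))
  # unpenalised columns survive
  pen <- c(FALSE, rep(TRUE, 9))
  fit2 <- fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 0.5, lambda = 50,
                         penalized = pen)
  expect_true(all(fit2$beta[-1] == 0))
  expect_gt(abs(fit2$beta[1]), 0.1)
})

test_that("the penalised objective trace is nonincreasing", {
  d <- make_logistic_data(n = 300, p = 12, seed = 9)
  fam <- rep(1:100, each = 3)
  fit <- fit_enet_mixed(d$X, d$y, groups = fam, lambda = 0.01)
  expect_true(all(diff(fit$objective) <= 1e-10))
  fit0 <- fit_enet_mixed(d$X, d$y, sigma = 0, lambda = 0.01)
  expect_true(all(diff(fit0$objective) <= 1e-10))
})

test_that("the L1 norm of penalised coefficients is nonincreasing in lambda", {
  d <- make_logistic_data(n = 250, p = 10, seed = 10)
  lams <- c(0, 1e-3, 1e-2, 0.05, 0.1, 0.5)
  l1 <- vapply(lams, function(l) {
    sum(abs(fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 0.1,
                           lambda = l)$beta))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("the family random-intercept SD is recovered across replicates", {
  set.seed(20)
  n_reps <- 20
  sig_hat <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    nf <- 300
    sizes <- sample(2:4, nf, replace = TRUE)
    fam <- rep(seq_len(nf), sizes)
    n <- length(fam)
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    u <- rnorm(nf, 0, 1)
    y <- rbinom(n, 1, plogis(0.2 + 0.5 * X[, 1] + u[fam]))
    sig_hat[r] <- fit_enet_mixed(X, y, groups = fam, alpha = 0.1,
                                 lambda = 1e-4)$sigma
  }
  se <- sd(sig_hat) / sqrt(n_reps)
  expect_lt(abs(mean(sig_hat) - 1), 3 * se)
})

test_that("invalid penalty settings and degenerate outcomes error", {
  d <- make_logistic_data(seed = 11)
  expect_error(fit_enet_mixed(d$X, d$y, sigma = 0, lambda = -1), "lambda")
  expect_error(fit_enet_mixed(d$X, d$y, sigma = 0, alpha = 2), "alpha")
  expect_error(fit_enet_mixed(d$X, rep(1, 200), sigma = 0), "binary")
  expect_error(fit_enet_mixed(d$X, d$y, groups = NULL), "groups")
})

test_that("grouped folds never split a family and are deterministic", {
  set.seed(12)
  for (r in 1:25) {
    nf <- sample(12:40, 1)
    fam <- rep(sprintf("F%02d", 1:nf), sample(1:5, nf, replace = TRUE))
    fold <- grouped_folds(fam, k = 10, seed = r)
    expect_true(all(tapply(fold, fam, function(x) length(unique(x))) == 1))
    expect_identical(fold, grouped_folds(fam, k = 10, seed = r))
  }
  expect_error(grouped_folds(rep("a", 5), k = 2), "Fewer families")
  expect_error(grouped_folds(c("a", "b", "c"), k = 2, seed = 1), NA)
})

test_that("grouped k-fold with singleton families at k = n is leave-one-out", {
  d <- make_logistic_data(n = 40, p = 3, seed = 13)
  fam <- as.character(1:40)
  cv <- grouped_kfold_predict(d$X, d$y, fam, k = 40, seed = 1, sigma = 0,
                              lambda = 0.05)
  expect_equal(sort(unique(cv$fold)), 1:40)
  expect_true(all(table(cv$fold) == 1))
  # manual LOO for one sample
  i <- which(cv$fold == cv$fold[5])
  fit <- fit_enet_mixed(d$X[-i, ], d$y[-i], sigma = 0, lambda = 0.05)
  expect_equal(cv$prob[i],
               unname(predict(fit, d$X[i, , drop = FALSE])), tolerance = 1e-8)
  # determinism
  cv2 <- grouped_kfold_predict(d$X, d$y, fam, k = 40, seed = 1, sigma = 0,
                               lambda = 0.05)
  expect_identical(cv, cv2)
})

test_that("AUC equals exhaustive pair counting, with ties at 1/2", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)   # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(4:100, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    s <- sample(round(runif(n), 2))   # coarse scores force ties
    expect_equal(roc_auc(s, y)$auc, oracle_pair_auc(s, y))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "Both classes")
})

test_that("the ROC staircase is monotone and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(80, 1, 0.4)
  s <- rnorm(80) + y
  r <- roc_auc(s, y)
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_true(all(diff(r$curve$specificity) <= 0))
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
})

test_that("bootstrap AUC comparison: identity, determinism and power", {
  set.seed(16)
  y <- rbinom(120, 1, 0.5)
  s <- rnorm(120) + 0.5 * y
  fam <- rep(sprintf("F%02d", 1:40), 3)
  same <- compare_auc_bootstrap(s, s, y, fam, n_reps = 200, seed = 3)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  noise <- rnorm(120)
  a <- compare_auc_bootstrap(s, noise, y, fam, n_reps = 200, seed = 4)
  b <- compare_auc_bootstrap(s, noise, y, fam, n_reps = 200, seed = 4)
  expect_identical(a$p, b$p)
  # strong signal vs noise separates decisively at n = 400
  set.seed(17)
  y2 <- rbinom(400, 1, 0.5)
  strong <- rnorm(400, mean = 2 * y2)   # true AUC ~ 0.92
  noise <- rnorm(400)
  fam2 <- rep(sprintf("F%03d", 1:100), 4)
  cmp <- compare_auc_bootstrap(strong, noise, y2, fam2, n_reps = 500, seed = 5)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$delta, 0.3)
})

test_that("full-vs-null run enforces the directly-measured-peaks-only rule", {
  cohort <- quick_cohort(n_families = 25, n_peaks = 6, seed = 18)
  rn <- preprocess_peaks(cohort$peak_table, cohort$metadata)
  tr <- rn
  names(tr)[2] <- "G1"   # a derived-trait column sneaks in
  tr <- peak_table(tr, state = "rank_normal")
  expect_error(run_full_vs_null(tr, cohort$metadata),
               "directly measured")
  pct <- preprocess_peaks(cohort$peak_table, cohort$metadata, until = "percent")
  expect_error(run_full_vs_null(pct, cohort$metadata), "rank_normal")
})

test_that("discrimination defaults are alpha = 0.1, lambda = 1e-4, 10 folds, 2000 bootstrap replicates", {
  expect_equal(formals(run_full_vs_null)$alpha, 0.1)
  expect_equal(formals(run_full_vs_null)$lambda, 1e-4)
  expect_equal(formals(run_full_vs_null)$k, 10)
  expect_equal(formals(run_full_vs_null)$n_boot, 2000)
})

test_that("a strong multi-peak effect separates full from null model", {
  cfg <- sim_config(n_families = 100, n_peaks = 12, seed = 19,
                    disease_effect = c(rep(0.5, 4), rep(-0.5, 2), rep(0, 6)))
  cohort <- simulate_cohort(cfg)
  rn <- preprocess_peaks(cohort$peak_table, cohort$metadata)
  res <- run_full_vs_null(rn, cohort$metadata, n_boot = 500, seed = 20)
  expect_gt(res$roc_full$auc, res$roc_null$auc)
  expect_lt(res$comparison$p, 0.05)
  # no family straddles folds
  expect_true(all(tapply(res$cv_full$fold, res$cv_full$family,
                         function(x) length(unique(x))) == 1))
  # tidy/glance accessors
  expect_equal(nrow(tidy(res)), 2)
  expect_true(glance(res)$auc_full > 0.5)
})
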