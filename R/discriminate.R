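# ---- penalised mixed-effects logistic regression -------------------------
#
# Model: logit P(y = 1) = b0 + X beta + u_f,  u_f ~ N(0, sigma^2) per family.
# Estimation: penalised quasi-likelihood -- an outer IRLS loop builds a
# weighted working least-squares problem; the inner loop is coordinate
# descent with an elastic-net penalty on the flagged fixed effects and a
# ridge-type shrinkage on the family intercepts induced by their Gaussian
# prior. The random-intercept variance is estimated by maximising the
# adaptive Gauss-Hermite marginal likelihood in sigma. The minimised
# objective (glmnet scaling) is
#   J = -(1/n) sum loglik + lambda * [alpha ||b_pen||_1 + (1-alpha)/2 ||b_pen||_2^2]
#       + (1/(2 n sigma^2)) sum u_f^2 .

# Gauss-Hermite nodes/weights for weight function exp(-x^2) (Golub-Welsch)
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# penalised objective at glmnet scaling
enet_objective <- function(beta0, beta, u, sigma, X, y, fam_idx, lambda,
                           alpha, penalized) {
  eta <- beta0 + drop(X %*% beta) + if (length(u)) u[fam_idx] else 0
  nll <- -mean(y * eta - log1p(exp(eta)))
  pen <- lambda * (alpha * sum(abs(beta[penalized])) +
                     (1 - alpha) / 2 * sum(beta[penalized]^2))
  reff <- if (sigma > 0 && length(u)) sum(u^2) / (2 * length(y) * sigma^2) else 0
  nll + pen + reff
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# one proximal-Newton step: IRLS working response, coordinate descent to
# convergence on the penalised weighted LS problem, then step-halving so the
# true penalised objective never increases
pql_step <- function(beta0, beta, u, sigma, X, y, fam_idx, n_fam, lambda,
                     alpha, penalized, inner_tol = 1e-6, max_sweeps = 1000) {
  n <- length(y)
  use_u <- sigma > 0
  eta <- beta0 + drop(X %*% beta) + if (use_u) u[fam_idx] else 0
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-6)
  z <- eta + (y - mu) / w
  sw <- sum(w)
  xsq <- colSums(X^2 * w) / n
  b0n <- beta0; bn <- beta; un <- u
  r <- z - (b0n + drop(X %*% bn) + if (use_u) un[fam_idx] else 0)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    # intercept
    new0 <- b0n + sum(w * r) / sw
    r <- r - (new0 - b0n); delta <- max(delta, abs(new0 - b0n)); b0n <- new0
    # fixed effects
    for (j in seq_along(bn)) {
      zj <- sum(w * r * X[, j]) / n + xsq[j] * bn[j]
      newb <- if (penalized[j]) {
        soft_threshold(zj, lambda * alpha) / (xsq[j] + lambda * (1 - alpha))
      } else zj / xsq[j]
      if (newb != bn[j]) {
        r <- r - (newb - bn[j]) * X[, j]
        delta <- max(delta, abs(newb - bn[j]))
        bn[j] <- newb
      }
    }
    # family intercepts: ridge from the Gaussian prior
    if (use_u) {
      swf <- rowsum_vec(w, fam_idx, n_fam)
      newu <- un + (rowsum_vec(w * r, fam_idx, n_fam) - un / sigma^2) /
        (swf + 1 / sigma^2)
      r <- r - (newu - un)[fam_idx]
      delta <- max(delta, max(abs(newu - un)))
      un <- newu
    }
    if (delta < inner_tol) break
  }
  # step-halving on the exact objective; if no descent step is found the
  # current point is kept (numerical convergence)
  j_old <- enet_objective(beta0, beta, u, sigma, X, y, fam_idx, lambda,
                          alpha, penalized)
  t <- 1
  accepted <- FALSE
  for (h in 1:25) {
    b0t <- beta0 + t * (b0n - beta0)
    bt <- beta + t * (bn - beta)
    ut <- u + t * (un - u)
    j_new <- enet_objective(b0t, bt, ut, sigma, X, y, fam_idx, lambda,
                            alpha, penalized)
    if (j_new <= j_old + 1e-12) { accepted <- TRUE; break }
    t <- t / 2
  }
  if (!accepted) {
    return(list(beta0 = beta0, beta = beta, u = u, objective = j_old,
                change = 0))
  }
  list(beta0 = b0t, beta = bt, u = ut, objective = j_new,
       change = max(abs(c(b0t - beta0, bt - beta, ut - u))))
}

rowsum_vec <- function(x, idx, n_groups) {
  drop(rowsum(x, idx, reorder = TRUE))[seq_len(n_groups)]
}

# adaptive Gauss-Hermite marginal log-likelihood in sigma, fixed effects held
# at eta_fixed; vectorised across families
agq_loglik <- function(sigma, eta_fixed, y, fam_idx, n_fam, gh) {
  if (sigma < 1e-6) {
    return(sum(y * eta_fixed - log1p(exp(eta_fixed))))
  }
  u <- rep(0, n_fam)
  for (it in 1:25) {                       # per-family posterior modes
    eta <- eta_fixed + u[fam_idx]
    mu <- plogis(eta)
    grad <- rowsum_vec(y - mu, fam_idx, n_fam) - u / sigma^2
    hess <- rowsum_vec(mu * (1 - mu), fam_idx, n_fam) + 1 / sigma^2
    step <- grad / hess
    u <- u + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- eta_fixed + u[fam_idx]
  mu <- plogis(eta)
  tau <- 1 / sqrt(rowsum_vec(mu * (1 - mu), fam_idx, n_fam) + 1 / sigma^2)
  K <- length(gh$nodes)
  logint <- matrix(NA_real_, n_fam, K)
  for (k in seq_len(K)) {
    uk <- u + sqrt(2) * tau * gh$nodes[k]
    etak <- eta_fixed + uk[fam_idx]
    ll <- rowsum_vec(y * etak - log1p(exp(etak)), fam_idx, n_fam)
    logint[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + ll +
      stats::dnorm(uk, 0, sigma, log = TRUE)
  }
  mx <- apply(logint, 1, max)
  sum(mx + log(rowSums(exp(logint - mx))) + log(sqrt(2) * tau))
}

#' Elastic-net penalised mixed-effects logistic regression
#'
#' Fits `logit P(y = 1) = b0 + X beta + u_family` with a Gaussian random
#' family intercept and an elastic-net penalty
#' `lambda * (alpha * ||beta||_1 + (1 - alpha) / 2 * ||beta||_2^2)` on the
#' flagged fixed effects (glycans penalised, covariates such as age and sex
#' not). Estimation alternates a penalised quasi-likelihood step
#' (IRLS outer, coordinate-descent elastic net inner, with step-halving so
#' the penalised objective is nonincreasing) with an adaptive Gauss-Hermite
#' update of the random-intercept SD. Defaults `alpha = 0.1`,
#' `lambda = 1e-4` give a near-unpenalised ridge-leaning fit.
#'
#' @param X Numeric predictor matrix (columns should be standardised; see
#'   [rank_normalize()]).
#' @param y Binary outcome (0/1, logical, or `"affected"`/`"unaffected"`).
#' @param groups Family ids, one per row of `X` (ignored when `sigma = 0`).
#' @param alpha Elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength, >= 0.
#' @param penalized Logical per column of `X`; default all penalised.
#' @param sigma `NULL` to estimate the random-intercept SD; a fixed value
#'   (e.g. `0` for a plain penalised logistic model) otherwise.
#' @param max_iter Maximum outer iterations.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param inner_tol Convergence tolerance of the coordinate-descent solve of
#'   each working least-squares subproblem.
#' @param gh_points Gauss-Hermite nodes for the variance update.
#' @return An object of class `t1d_enet_mixed` with elements `beta0`,
#'   `beta`, `u` (named by family), `sigma`, `objective` (nonincreasing
#'   trace of the final fixed-variance optimisation), `converged`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rbinom(200, 1, plogis(X[, 1]))
#' fit <- fit_enet_mixed(X, y, groups = rep(1:50, each = 4), lambda = 0.01)
#' coef(fit)
#' @export
fit_enet_mixed <- function(X, y, groups = NULL, alpha = 0.1, lambda = 1e-4,
                           penalized = NULL, sigma = NULL, max_iter = 50,
                           tol = 1e-6, inner_tol = 1e-6, gh_points = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- status_binary(y)
  if (!all(y %in% 0:1) || length(unique(y)) < 2) {
    abort("`y` must be binary with both classes present.")
  }
  if (lambda < 0) abort("`lambda` must be >= 0.")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  penalized <- penalized %||% rep(TRUE, ncol(X))
  estimate_sigma <- is.null(sigma)
  if (estimate_sigma || sigma > 0) {
    if (is.null(groups)) abort("`groups` is required for a random intercept.")
    fam <- factor(groups)
    if (length(fam) != nrow(X)) abort("`groups` must cover all samples.")
  } else {
    fam <- factor(rep("all", nrow(X)))
  }
  fam_idx <- as.integer(fam)
  n_fam <- nlevels(fam)
  gh <- gauss_hermite(gh_points)

  beta0 <- qlogis(mean(pmin(pmax(mean(y), 0.01), 0.99)))
  beta <- rep(0, ncol(X))
  u <- rep(0, n_fam)
  sig <- if (estimate_sigma) 0.5 else sigma

  sigma_trace <- numeric()
  if (estimate_sigma) {
    for (it in 1:6) {
      for (s in 1:2) {
        st <- pql_step(beta0, beta, u, sig, X, y, fam_idx, n_fam, lambda,
                       alpha, penalized, inner_tol = inner_tol)
        beta0 <- st$beta0; beta <- st$beta; u <- st$u
        if (st$change < tol) break
      }
      eta_fixed <- beta0 + drop(X %*% beta)
      opt <- optimize(function(ls) -agq_loglik(exp(ls), eta_fixed, y,
                                               fam_idx, n_fam, gh),
                      interval = log(c(1e-3, 5)), tol = 0.005)
      new_sig <- exp(opt$minimum)
      sigma_trace <- c(sigma_trace, new_sig)
      done <- abs(new_sig - sig) < 0.005 * (1 + sig)
      sig <- new_sig
      if (done && it > 1) break
    }
    if (sig <= 1.5e-3) { sig <- 0; u <- rep(0, n_fam) }  # boundary: no variance
  }

  # final optimisation at fixed sigma, objective tracked (nonincreasing)
  objective <- enet_objective(beta0, beta, u, sig, X, y, fam_idx, lambda,
                              alpha, penalized)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- pql_step(beta0, beta, u, sig, X, y, fam_idx, n_fam, lambda,
                   alpha, penalized, inner_tol = inner_tol)
    beta0 <- st$beta0; beta <- st$beta; u <- st$u
    objective <- c(objective, st$objective)
    if (st$change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(paste0("fit_enet_mixed did not converge in ", max_iter,
                " outer iterations; returning the last iterate."))
  }
  structure(list(beta0 = beta0, beta = setNames(beta, colnames(X)),
                 u = setNames(u, levels(fam)), sigma = sig,
                 sigma_estimated = estimate_sigma, sigma_trace = sigma_trace,
                 alpha = alpha, lambda = lambda, penalized = penalized,
                 objective = objective, converged = converged,
                 n = nrow(X), n_families = n_fam),
            class = "t1d_enet_mixed")
}

#' @export
coef.t1d_enet_mixed <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' @method print t1d_enet_mixed
#' @export
print.t1d_enet_mixed <- function(x, ...) {
  cat("<penalised mixed logistic> n=", x$n, ", families=", x$n_families,
      ", alpha=", x$alpha, ", lambda=", format(x$lambda),
      ", sigma_fam=", round(x$sigma, 3),
      if (x$sigma_estimated) " (estimated)" else " (fixed)",
      ", nonzero=", sum(x$beta != 0), "/", length(x$beta), "\n", sep = "")
  invisible(x)
}

#' Predict from a penalised mixed logistic model
#'
#' Random intercepts are used for families seen in training and set to 0
#' for unseen families (the population-level prediction used for
#' cross-validated samples).
#'
#' @param object A `t1d_enet_mixed` fit.
#' @param newx Predictor matrix with the training columns.
#' @param groups Optional family ids for `newx`.
#' @param type `"response"` (probability) or `"link"`.
#' @param ... Unused.
#' @export
predict.t1d_enet_mixed <- function(object, newx, groups = NULL,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- object$beta0 + drop(as.matrix(newx)[, names(object$beta), drop = FALSE]
                             %*% object$beta)
  if (!is.null(groups) && object$sigma > 0) {
    m <- match(as.character(groups), names(object$u))
    eta <- eta + ifelse(is.na(m), 0, object$u[m])
  }
  if (type == "response") plogis(eta) else eta
}

#' @export
tidy.t1d_enet_mixed <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$beta)),
         estimate = c(x$beta0, unname(x$beta)),
         penalized = c(FALSE, x$penalized))
}

#' @export
glance.t1d_enet_mixed <- function(x, ...) {
  tibble(n = x$n, n_families = x$n_families, sigma_fam = x$sigma,
         alpha = x$alpha, lambda = x$lambda,
         nonzero = sum(x$beta != 0), converged = x$converged,
         objective = x$objective[length(x$objective)])
}

# ---- family-grouped cross-validation -------------------------------------

#' Assign families to cross-validation folds
#'
#' Folds partition families, never samples: all siblings of a family share
#' a fold, so no within-family information leaks between training and test
#' sets.
#'
#' @param groups Family ids, one per sample.
#' @param k Number of folds (>= 2, <= number of families).
#' @param seed Integer seed for the family shuffle.
#' @return Integer fold id per sample.
#' @export
grouped_folds <- function(groups, k = 10, seed = 1) {
  fams <- unique(as.character(groups))
  if (k < 2) abort("`k` must be >= 2.")
  if (length(fams) < k) {
    abort(paste0("Fewer families (", length(fams), ") than folds (", k, ")."))
  }
  set.seed(seed)
  shuffled <- sample(fams)
  fold_of <- setNames(rep_len(seq_len(k), length(fams)), shuffled)
  unname(fold_of[as.character(groups)])
}

#' Out-of-fold predictions under family-grouped k-fold cross-validation
#'
#' Each sample's probability is predicted by the model fitted without its
#' family's fold; random intercepts of unseen families are 0.
#'
#' @inheritParams fit_enet_mixed
#' @param k Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param ... Passed to [fit_enet_mixed()].
#' @return A tibble: `row`, `fold`, `y`, `prob`, `family`.
#' @export
grouped_kfold_predict <- function(X, y, groups, alpha = 0.1, lambda = 1e-4,
                                  penalized = NULL, k = 10, seed = 1, ...) {
  X <- as.matrix(X)
  y <- status_binary(y)
  fold <- grouped_folds(groups, k = k, seed = seed)
  prob <- rep(NA_real_, nrow(X))
  for (f in sort(unique(fold))) {
    train <- fold != f
    fit <- fit_enet_mixed(X[train, , drop = FALSE], y[train],
                          groups = groups[train], alpha = alpha,
                          lambda = lambda, penalized = penalized, ...)
    prob[!train] <- predict(fit, X[!train, , drop = FALSE],
                            groups = groups[!train])
  }
  tibble(row = seq_len(nrow(X)), fold = fold, y = y, prob = prob,
         family = as.character(groups))
}

# ---- ROC / AUC -----------------------------------------------------------

#' ROC curve and AUC
#'
#' AUC is computed via the Mann-Whitney U identity (ties contribute 1/2):
#' the probability that a random affected sample scores above a random
#' unaffected one. The curve is the monotone staircase over all distinct
#' score thresholds.
#'
#' @param scores Numeric classifier scores (higher = more likely affected).
#' @param labels Binary labels (0/1, logical or `"affected"`/`"unaffected"`).
#' @return An object of class `t1d_roc` with `auc`, `n_pos`, `n_neg` and a
#'   `curve` tibble (`threshold`, `sensitivity`, `specificity`).
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, labels) {
  y <- status_binary(labels)
  if (length(scores) != length(y)) abort("`scores` and `labels` differ in length.")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n_neg, numeric(1))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg,
                 curve = tibble(threshold = thr, sensitivity = sens,
                                specificity = spec)),
            class = "t1d_roc")
}

#' @method print t1d_roc
#' @export
print.t1d_roc <- function(x, ...) {
  cat("<ROC> AUC = ", round(x$auc, 3), " (", x$n_pos, " affected / ",
      x$n_neg, " unaffected)\n", sep = "")
  invisible(x)
}

auc_only <- function(scores, y, n_pos, n_neg) {
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Resamples clusters (families by default, respecting the sibling
#' correlation; optionally single samples) with replacement, recomputes
#' both AUCs per replicate, and reports the percentile CI of the AUC
#' difference and a two-sided p-value from the normal approximation to the
#' bootstrap delta distribution. Replicates with a single outcome class are
#' redrawn and counted.
#'
#' @param scores_full,scores_null Paired scores on identical samples.
#' @param labels Binary labels.
#' @param groups Family ids (required for `resample = "family"`).
#' @param n_reps Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param resample `"family"` (default) or `"sample"`.
#' @return An object of class `t1d_auc_comparison`: `auc_full`, `auc_null`,
#'   `delta`, `ci` (percentile), `p`, `n_replicates`, `n_redrawn`.
#' @export
compare_auc_bootstrap <- function(scores_full, scores_null, labels,
                                  groups = NULL, n_reps = 2000, seed = 1,
                                  resample = c("family", "sample")) {
  resample <- match.arg(resample)
  y <- status_binary(labels)
  if (length(scores_full) != length(y) || length(scores_null) != length(y)) {
    abort("Scores must be paired on identical samples.")
  }
  roc_f <- roc_auc(scores_full, y)
  roc_n <- roc_auc(scores_null, y)
  delta_obs <- roc_f$auc - roc_n$auc
  if (resample == "family") {
    if (is.null(groups)) abort("`groups` is required for family resampling.")
    cluster_idx <- split(seq_along(y), as.character(groups))
  } else {
    cluster_idx <- as.list(seq_along(y))
  }
  nc <- length(cluster_idx)
  set.seed(seed)
  deltas <- numeric(n_reps)
  n_redrawn <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- unlist(cluster_idx[sample.int(nc, nc, replace = TRUE)],
                    use.names = FALSE)
      yb <- y[idx]
      np <- sum(yb == 1); nn <- length(yb) - np
      if (np > 0 && nn > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10000L) abort("Bootstrap cannot find two-class replicates.")
    }
    deltas[b] <- auc_only(scores_full[idx], yb, np, nn) -
      auc_only(scores_null[idx], yb, np, nn)
  }
  sd_d <- sd(deltas)
  p <- if (sd_d == 0) {
    if (delta_obs == 0) 1 else 0
  } else {
    2 * pnorm(-abs(delta_obs) / sd_d)
  }
  structure(list(auc_full = roc_f$auc, auc_null = roc_n$auc,
                 delta = delta_obs,
                 ci = unname(quantile(deltas, c(0.025, 0.975))),
                 p = p, n_replicates = n_reps, n_redrawn = n_redrawn,
                 deltas = deltas, resample = resample),
            class = "t1d_auc_comparison")
}

#' @method print t1d_auc_comparison
#' @export
print.t1d_auc_comparison <- function(x, ...) {
  cat("<AUC comparison> full = ", round(x$auc_full, 3),
      ", null = ", round(x$auc_null, 3),
      ", delta = ", round(x$delta, 3),
      " [", round(x$ci[1], 3), ", ", round(x$ci[2], 3), "]",
      ", p = ", format(x$p, digits = 3),
      " (", x$n_replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' @export
tidy.t1d_auc_comparison <- function(x, ...) {
  tibble(model = c("full", "null"), auc = c(x$auc_full, x$auc_null))
}

#' @export
glance.t1d_auc_comparison <- function(x, ...) {
  tibble(auc_full = x$auc_full, auc_null = x$auc_null, delta = x$delta,
         ci_lo = x$ci[1], ci_hi = x$ci[2], p = x$p,
         n_replicates = x$n_replicates)
}

# ---- full vs null discrimination analysis --------------------------------

#' Glycan-based discrimination: full vs null model
#'
#' Fits two elastic-net penalised mixed logistic models under
#' family-grouped 10-fold cross-validation -- a full model (sex, age and
#' all standardised directly measured glycan peaks as fixed effects, family
#' as random intercept) and a null model without the glycan peaks -- then
#' compares the out-of-fold AUCs with a paired family bootstrap. Only
#' directly measured peaks (columns `GP<number>`) may enter as glycan
#' predictors; derived traits are rejected.
#'
#' @param table Peak table in state `"rank_normal"`.
#' @param metadata Metadata with `sample_id, family_id, sex, age, status`.
#' @param alpha,lambda Elastic-net mixing and penalty (defaults 0.1, 1e-4).
#' @param k Cross-validation folds (default 10).
#' @param n_boot Bootstrap replicates for the AUC comparison (default 2000).
#' @param seed Seed for fold assignment and the bootstrap.
#' @param random_effect `TRUE` (default) estimates a family random
#'   intercept; `FALSE` fits plain penalised logistic models.
#' @param ... Passed to [fit_enet_mixed()].
#' @return An object of class `t1d_discrimination`: `roc_full`, `roc_null`
#'   ([roc_auc()] objects), `comparison` ([compare_auc_bootstrap()]),
#'   out-of-fold prediction tibbles `cv_full`, `cv_null`.
#' @export
run_full_vs_null <- function(table, metadata, alpha = 0.1, lambda = 1e-4,
                             k = 10, n_boot = 2000, seed = 1,
                             random_effect = TRUE, ...) {
  require_state(table, "rank_normal", "run_full_vs_null")
  pk <- peak_ids(table)
  bad <- pk[!grepl("^GP[0-9]+$", pk)]
  if (length(bad)) {
    abort(paste0("Only directly measured glycan peaks (GP1..GPn) may be used ",
                 "as predictors; derived traits or other columns found: ",
                 paste(bad, collapse = ", ")))
  }
  metadata <- metadata[match(table$sample_id, metadata$sample_id), ]
  check_metadata_match(table, metadata)
  y <- status_binary(metadata$status)
  covar <- cbind(age = standardize(metadata$age),
                 sexM = as.numeric(metadata$sex == "M"))
  X_full <- cbind(peak_matrix(table), covar)
  pen_full <- c(rep(TRUE, length(pk)), FALSE, FALSE)
  sigma <- if (random_effect) NULL else 0
  cv_full <- grouped_kfold_predict(X_full, y, metadata$family_id,
                                   alpha = alpha, lambda = lambda,
                                   penalized = pen_full, k = k, seed = seed,
                                   sigma = sigma, ...)
  cv_null <- grouped_kfold_predict(covar, y, metadata$family_id,
                                   alpha = alpha, lambda = lambda,
                                   penalized = c(FALSE, FALSE), k = k,
                                   seed = seed, sigma = sigma, ...)
  comparison <- compare_auc_bootstrap(cv_full$prob, cv_null$prob, y,
                                      groups = metadata$family_id,
                                      n_reps = n_boot, seed = seed)
  structure(list(roc_full = roc_auc(cv_full$prob, y),
                 roc_null = roc_auc(cv_null$prob, y),
                 comparison = comparison,
                 cv_full = cv_full, cv_null = cv_null,
                 alpha = alpha, lambda = lambda, k = k, seed = seed),
            class = "t1d_discrimination")
}

#' @method print t1d_discrimination
#' @export
print.t1d_discrimination <- function(x, ...) {
  cat("<discrimination: full vs null>\n")
  cat("  full  AUC = ", round(x$roc_full$auc, 3), "\n", sep = "")
  cat("  null  AUC = ", round(x$roc_null$auc, 3), "\n", sep = "")
  cat("  delta = ", round(x$comparison$delta, 3),
      ", bootstrap p = ", format(x$comparison$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.t1d_discrimination <- function(x, ...) {
  dplyr::bind_rows(
    tibble(model = "full", auc = x$roc_full$auc),
    tibble(model = "null", auc = x$roc_null$auc))
}

#' @export
glance.t1d_discrimination <- function(x, ...) glance(x$comparison)
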