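# Independent oracles used by the tests. These deliberately re-derive the
# quantities with different code paths (direct linear algebra, exhaustive
# enumeration, textbook formulas) rather than calling package internals.

# unpenalised logistic regression via Newton iterations on the normal
# equations (independent IRLS)
oracle_irls_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(crossprod(X1, X1 * w), crossprod(X1, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# AUC by exhaustive enumeration of affected/unaffected pairs
oracle_pair_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# parametric empirical-Bayes location/scale batch adjustment written out
# from the model definition: per-feature standardisation against the
# batch-size-weighted grand mean and pooled variance, per-batch moment
# estimates, EB shrinkage toward batch-level hyperpriors (normal prior on
# the location, inverse-gamma on the scale, method-of-moments
# hyperparameters), iterative joint solution, adjust, back-transform.
# m: samples x features, batch: factor-like
oracle_eb_combat <- function(m, batch) {
  batch <- factor(batch)
  batches <- levels(batch)
  nb <- table(batch)
  n <- nrow(m)
  bmeans <- apply(m, 2, function(x) tapply(x, batch, mean))  # batches x features
  grand <- drop((nb / n) %*% bmeans)
  varp <- colMeans((m - bmeans[batch, , drop = FALSE])^2)
  Z <- sweep(sweep(m, 2, grand), 2, sqrt(varp), `/`)
  adj <- Z
  for (bi in seq_along(batches)) {
    idx <- batch == batches[bi]
    Zb <- Z[idx, , drop = FALSE]
    g <- colMeans(Zb)
    d <- apply(Zb, 2, stats::var)
    gbar <- mean(g); t2 <- stats::var(g)
    md <- mean(d); s2 <- stats::var(d)
    a_prior <- (2 * s2 + md^2) / s2
    b_prior <- (md * s2 + md^3) / s2
    g_star <- g; d_star <- d
    for (it in 1:500) {
      g_new <- (nb[bi] * t2 * g + d_star * gbar) / (nb[bi] * t2 + d_star)
      ss <- colSums((Zb - matrix(g_new, nrow(Zb), ncol(Zb), byrow = TRUE))^2)
      d_new <- (b_prior + 0.5 * ss) / (nrow(Zb) / 2 + a_prior - 1)
      change <- max(abs(c(g_new - g_star, d_new - d_star)))
      g_star <- g_new; d_star <- d_new
      if (change < 1e-12) break
    }
    adj[idx, ] <- sweep(sweep(Zb, 2, g_star), 2, sqrt(d_star), `/`)
  }
  sweep(sweep(adj, 2, sqrt(varp), `*`), 2, grand, `+`)
}

# Monte-Carlo oracle: draws log-percentages directly from the generative
# equations (baseline + family intercept + batch shift + effects + residual
# on log-areas, then compositional renormalisation)
oracle_mc_log_pct_diff <- function(baseline, disease_effect, peak,
                                   family_sd, batch_sd, resid_sd,
                                   n_draws = 1e5, seed = 424242) {
  set.seed(seed)
  p <- length(baseline)
  draw <- function(affected) {
    loga <- matrix(baseline, n_draws, p, byrow = TRUE) +
      matrix(rnorm(n_draws * p, 0, family_sd), n_draws, p) +
      matrix(rnorm(n_draws * p, 0, batch_sd), n_draws, p) +
      outer(rep(as.numeric(affected), n_draws), disease_effect) +
      matrix(rnorm(n_draws * p, 0, resid_sd), n_draws, p)
    a <- exp(loga)
    log(100 * a[, peak] / rowSums(a))
  }
  aff <- draw(TRUE)
  un <- draw(FALSE)
  list(diff = mean(aff) - mean(un),
       se = sqrt(stats::var(aff) / n_draws + stats::var(un) / n_draws))
}

# small convenience: simulated cohort at defaults with overridable arguments
quick_cohort <- function(...) simulate_cohort(sim_config(...))
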