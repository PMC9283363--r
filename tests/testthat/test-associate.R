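test_that("age groups use sex-specific pubertal cut-offs", {
  expect_equal(as.character(assign_age_group(4.2, "F")), "child")
  expect_equal(as.character(assign_age_group(14.3, "M")), "pubertal")
  expect_equal(as.character(assign_age_group(16.0, "F")), "postpubertal")
  # 12-year-olds straddle the sex-specific boundaries
  expect_equal(as.character(assign_age_group(12, "F")), "pubertal")
  expect_equal(as.character(assign_age_group(12, "M")), "prepubertal")
  # boundaries are inclusive on the right
  expect_equal(as.character(assign_age_group(c(6, 11, 15), "F")),
               c("prepubertal", "pubertal", "postpubertal"))
  expect_true(is.ordered(assign_age_group(c(3, 8), c("F", "M"))))
  expect_error(assign_age_group(0, "F"), "positive")
})

test_that("BH adjustment: forced arithmetic, identity at m = 1, properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(2)
  p <- runif(1000)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # q nondecreasing in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("sex-by-age model emits the full contrast grid with BH q-values", {
  set.seed(41)
  n <- 480
  d <- tibble::tibble(
    sex = rep(c("F", "M"), n / 2),
    age = runif(n, 1, 19),
    glycan = rnorm(n))
  d$age_group <- assign_age_group(d$age, d$sex)
  fit <- fit_sex_age_model(d, glycan)
  ct <- tidy(fit)
  # 2 sexes x C(4,2) age contrasts + 4 age groups x 1 sex contrast = 16
  expect_equal(nrow(ct), 16)
  expect_true(all(ct$q >= ct$p))
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("a pure sex shift is detected in every age group", {
  set.seed(42)
  n <- 3200   # >=200 per sex within each age group: two-sample t power ~ 1
  d <- tibble::tibble(
    sex = rep(c("F", "M"), n / 2),
    age = runif(n, 1, 19))
  d$age_group <- assign_age_group(d$age, d$sex)
  d$glycan <- rnorm(n, sd = 1) + 0.5 * (d$sex == "M")
  ct <- tidy(fit_sex_age_model(d, glycan))
  sex_ct <- ct[ct$family == "sex_within_age", ]
  expect_equal(nrow(sex_ct), 4)
  expect_true(all(abs(sex_ct$estimate) > 0.1))
  cell_n <- min(table(d$sex, d$age_group))
  power <- power.t.test(n = cell_n, delta = 0.5, sd = 1,
                        sig.level = 0.05)$power
  expect_gt(power, 0.99)  # the analytic power justifies the hard assertion
  expect_true(all(sex_ct$q < 0.05))
})

test_that("null sex-age data keeps the contrast false-positive rate nominal", {
  set.seed(43)
  n_reps <- 150
  any_rej <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    n <- 160
    d <- tibble::tibble(sex = rep(c("F", "M"), n / 2), age = runif(n, 1, 19))
    d$age_group <- assign_age_group(d$age, d$sex)
    d$glycan <- rnorm(n)
    ct <- suppressWarnings(tidy(fit_sex_age_model(d, glycan)))
    any_rej[r] <- mean(ct$q < 0.05)
  }
  # per-contrast rejection rate under BH at q < 0.05 stays at/below ~0.05
  rate <- mean(any_rej)
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("degenerate designs: single age group yields only sex contrasts, empty cells error", {
  set.seed(44)
  d <- tibble::tibble(sex = rep(c("F", "M"), 30), age = runif(60, 1, 5))
  d$age_group <- assign_age_group(d$age, d$sex)   # all children
  d$glycan <- rnorm(60)
  ct <- tidy(fit_sex_age_model(d, glycan))
  expect_equal(nrow(ct), 1)
  d2 <- tibble::tibble(sex = c(rep("F", 30), rep("M", 30)),
                       age = c(runif(30, 1, 5), runif(30, 14, 16)),
                       glycan = rnorm(60))
  d2$age_group <- assign_age_group(d2$age, d2$sex)
  expect_error(fit_sex_age_model(d2, glycan), "Empty design cells")
})

test_that("censored model: coefficients recovered without bias across replicates", {
  set.seed(45)
  n_reps <- 60
  est <- matrix(NA_real_, n_reps, 3)
  for (r in seq_len(n_reps)) {
    d <- simulate_censored_response(300, b0 = 0, b1 = 0.59, b2 = 0.8)
    f <- fit_censored_autoantibody_model(d, glycan, level,
                                         loq = max(d$level))
    est[r, ] <- c(f$b0, f$b1, f$b2)
  }
  truth <- c(0, 0.59, 0.8)
  se <- apply(est, 2, sd) / sqrt(n_reps)
  expect_true(all(abs(colMeans(est) - truth) < 3 * se))
})

test_that("censored model degenerates gracefully and is translation-equivariant", {
  set.seed(46)
  d <- simulate_censored_response(200, b1 = 0.6, b2 = 1, loq = 1e9)
  expect_warning(f <- fit_censored_autoantibody_model(d, glycan, level,
                                                      loq = 1e9),
                 "b2 dropped")
  expect_true(is.na(f$b2))
  expect_equal(f$n_censored, 0)
  # with no censoring the fit equals an ordinary regression on the level
  ols <- lm(glycan ~ level + factor(sex) + age, data = d)
  expect_equal(f$b1, unname(coef(ols)["level"]), tolerance = 1e-10)

  # shifting level and LOQ by the same constant: the slope b1 is invariant,
  # the intercept absorbs -shift * b1, and b2 compensates so that the fitted
  # value beyond the LOQ (b0 + b2) is unchanged
  d2 <- simulate_censored_response(300, b1 = 0.5, b2 = 0.9)
  loq <- max(d2$level)
  f1 <- fit_censored_autoantibody_model(d2, glycan, level, loq = loq)
  d3 <- dplyr::mutate(d2, level = level + 5)
  f2 <- fit_censored_autoantibody_model(d3, glycan, level, loq = loq + 5)
  expect_equal(f1$b1, f2$b1, tolerance = 1e-9)
  expect_equal(f1$b0, f2$b0 + 5 * f2$b1, tolerance = 1e-6)
  expect_equal(f1$b0 + f1$b2, f2$b0 + f2$b2, tolerance = 1e-6)
})

test_that("censored model with everything quantified equals plain least squares (normal equations)", {
  set.seed(47)
  d <- simulate_censored_response(150, b1 = 0.4, b2 = 0.7, loq = 1e9,
                                  sex_effect = 0, age_slope = 0)
  f <- suppressWarnings(
    fit_censored_autoantibody_model(d, glycan, level, loq = 1e9,
                                    sex = NULL, age = NULL))
  # independent normal-equations solve
  A <- cbind(1, d$level)
  beta <- solve(crossprod(A), crossprod(A, d$glycan))
  expect_equal(unname(c(f$b0, f$b1)), drop(beta), tolerance = 1e-10)
})

test_that("lower-tail censoring convention flips the indicator", {
  set.seed(48)
  cc <- rlnorm(300)
  loq <- quantile(cc, 0.3)
  d <- tibble::tibble(level = pmax(cc, loq),
                      glycan = 0.5 * pmax(cc, loq) + rnorm(300, 0, 0.1),
                      sex = "F", age = 10)
  f <- fit_censored_autoantibody_model(d, glycan, level, loq = loq,
                                       sex = NULL, age = NULL,
                                       censor_side = "lower")
  expect_equal(f$n_uncensored, sum(cc > loq))
})

test_that("autoantibody count trend is recovered and degenerate input errors", {
  set.seed(49)
  n_reps <- 60
  est <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    n <- 300
    cnt <- sample(1:4, n, replace = TRUE)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- runif(n, 1, 19)
    gly <- -0.93 * cnt + 0.2 * (sex == "M") + 0.01 * age + rnorm(n)
    d <- tibble::tibble(glycan = gly, count = cnt, sex = sex, age = age)
    est[r] <- fit_autoantibody_count_model(d, glycan, count)$beta
  }
  se <- sd(est) / sqrt(n_reps)
  expect_lt(abs(mean(est) + 0.93), 3 * se)

  # null: type-I error near nominal
  set.seed(50)
  pvals <- replicate(200, {
    n <- 120
    d <- tibble::tibble(glycan = rnorm(n),
                        count = sample(1:4, n, replace = TRUE),
                        sex = sample(c("F", "M"), n, replace = TRUE),
                        age = runif(n, 1, 19))
    fit_autoantibody_count_model(d, glycan, count)$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200))

  d_bad <- tibble::tibble(glycan = rnorm(10), count = rep(2, 10),
                          sex = "F", age = 5)
  expect_error(fit_autoantibody_count_model(d_bad, glycan, count),
               "distinct")
})

test_that("disease association: OR centred at 1 with valid CI coverage under the null", {
  set.seed(51)
  n_reps <- 120
  cover <- logical(n_reps)
  logors <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cohort <- quick_cohort(n_families = 60, n_peaks = 2,
                           family_intercept_sd = 0, seed = 60000 + r)
    rn <- preprocess_peaks(cohort$peak_table, cohort$metadata,
                           until = "percent")
    tab <- rank_normalize(rn)
    res <- disease_association(tab, cohort$metadata, glycans = "GP1",
                               method = "glm")
    cover[r] <- res$ci_lo <= 1 && res$ci_hi >= 1
    logors[r] <- log(res$or)
  }
  expect_lt(abs(mean(logors)), 3 * sd(logors) / sqrt(n_reps))
  expect_gt(mean(cover), 0.95 - 2.58 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("disease association recovers a true per-SD log-OR with family clustering", {
  set.seed(52)
  nf <- 200
  sizes <- sample(2:3, nf, replace = TRUE)
  fam <- rep(sprintf("F%03d", 1:nf), sizes)
  n <- length(fam)
  g <- rnorm(n)
  age <- runif(n, 1, 19)
  sex <- sample(c("F", "M"), n, TRUE)
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * g))
  tab <- peak_table(tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                                   GP1 = g, GP2 = rnorm(n)),
                    state = "rank_normal")
  md <- tibble::tibble(sample_id = tab$sample_id, family_id = fam, sex = sex,
                       age = age, status = ifelse(y == 1, "affected",
                                                  "unaffected"))
  res <- disease_association(tab, md, glycans = "GP1")
  # g has sd ~1 so the per-SD log-OR should be near 0.7
  expect_lt(abs(log(res$or) - 0.7 * sd(g)), 3 * res$se)
})

test_that("family-free simulations agree with plain logistic regression", {
  set.seed(53)
  n <- 300
  g <- rnorm(n)
  age <- runif(n, 1, 19); sex <- sample(c("F", "M"), n, TRUE)
  y <- rbinom(n, 1, plogis(0.5 * g))
  tab <- peak_table(tibble::tibble(sample_id = as.character(1:n), GP1 = g,
                                   GP2 = rnorm(n)), state = "rank_normal")
  md <- tibble::tibble(sample_id = tab$sample_id,
                       family_id = tab$sample_id,  # every sample its own family
                       sex = sex, age = age,
                       status = ifelse(y == 1, "affected", "unaffected"))
  res <- disease_association(tab, md, glycans = "GP1", method = "glm")
  gs <- (g - mean(g)) / sd(g)
  ref <- glm(y ~ gs + age + I(sex == "M"), family = binomial)
  expect_lt(abs(log(res$or) - coef(ref)["gs"]), 1e-3)
})

test_that("perfect separation is flagged and handled with a penalised fit", {
  n <- 60
  y <- rep(0:1, each = n / 2)
  tab <- peak_table(tibble::tibble(sample_id = as.character(1:n),
                                   GP1 = as.numeric(y), GP2 = rnorm(n)),
                    state = "rank_normal")
  md <- tibble::tibble(sample_id = tab$sample_id, family_id = tab$sample_id,
                       sex = rep(c("F", "M"), n / 2), age = runif(n, 1, 19),
                       status = ifelse(y == 1, "affected", "unaffected"))
  res <- suppressWarnings(disease_association(tab, md, glycans = "GP1",
                                              method = "glm"))
  expect_true(res$separation)
  expect_equal(res$method, "firth")
  expect_true(is.finite(res$or))
})

test_that("per-glycan results are order-independent", {
  set.seed(54)
  cohort <- quick_cohort(n_families = 50, n_peaks = 4, seed = 55)
  rn <- rank_normalize(preprocess_peaks(cohort$peak_table, cohort$metadata,
                                        until = "percent"))
  res1 <- disease_association(rn, cohort$metadata, method = "glm")
  perm <- c("GP3", "GP1", "GP4", "GP2")
  rn2 <- peak_table(rn[, c("sample_id", perm)], state = "rank_normal")
  res2 <- disease_association(rn2, cohort$metadata, method = "glm")
  expect_equal(res2$or, res1$or[match(perm, res1$glycan)])
  expect_equal(res2$q, res1$q[match(perm, res1$glycan)])
})
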