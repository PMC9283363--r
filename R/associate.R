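#' Assign pubertal age groups
#'
#' Maps age at sampling to an ordered pubertal stage with sex-specific
#' cut-offs: females child < 6 <= pre-pubertal < 11 <= pubertal < 15 <=
#' post-pubertal; males child < 6 <= pre-pubertal < 13 <= pubertal < 17 <=
#' post-pubertal.
#'
#' @param age Age in years (> 0), vectorised.
#' @param sex `"F"`/`"M"` (vectorised, recycled if scalar).
#' @param cutoffs Named list with numeric length-3 elements `F` and `M`
#'   giving the three boundaries.
#' @return Ordered factor with levels `child < prepubertal < pubertal <
#'   postpubertal`.
#' @examples
#' assign_age_group(c(4.2, 14.3, 16), c("F", "M", "F"))
#' @export
assign_age_group <- function(age, sex,
                             cutoffs = list(F = c(6, 11, 15),
                                            M = c(6, 13, 17))) {
  if (any(age <= 0)) abort("Ages must be positive.")
  if (length(sex) == 1) sex <- rep(sex, length(age))
  if (!all(sex %in% c("F", "M"))) abort("`sex` must be 'F' or 'M'.")
  lv <- c("child", "prepubertal", "pubertal", "postpubertal")
  idx <- vapply(seq_along(age), function(i) {
    cut <- cutoffs[[sex[i]]]
    1L + sum(age[i] >= cut)
  }, integer(1))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement
#' (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

standardize <- function(x) {
  s <- sd(x)
  if (s == 0) abort("Cannot standardise a constant glycan vector.")
  (x - mean(x)) / s
}

#' Sex-by-age-group model for one glycan
#'
#' Least-squares fit of `glycan ~ sex * age_group` on rank-normalised glycan
#' values, followed by estimated marginal means per design cell and
#' post-hoc pairwise t contrasts: between age groups within each sex, and
#' between sexes within each age group, with BH adjustment across all
#' contrasts.
#'
#' @param data Data frame with the glycan and covariate columns.
#' @param glycan Column (tidy-eval) holding the rank-normalised glycan.
#' @param sex,age_group Columns holding sex (`"F"`/`"M"`) and the ordered
#'   age group (see [assign_age_group()]); defaults to columns named `sex`
#'   and `age_group`.
#' @return An object of class `t1d_sexage_fit`; `tidy()` returns the
#'   contrast table (contrast, stratum, estimate, SE, t, df, p, q),
#'   `glance()` the model-level summary.
#' @export
fit_sex_age_model <- function(data, glycan, sex = sex, age_group = age_group) {
  df <- tibble(
    glycan = dplyr::pull(data, {{ glycan }}),
    sex = factor(dplyr::pull(data, {{ sex }})),
    age_group = factor(dplyr::pull(data, {{ age_group }}), ordered = FALSE)
  )
  df <- droplevels(df)
  cells <- table(df$sex, df$age_group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(i) paste(rownames(cells)[i[1]],
                                             colnames(cells)[i[2]], sep = ":"))
    abort(paste0("Empty design cells: ", paste(lab, collapse = ", ")))
  }
  multi_age <- nlevels(df$age_group) > 1
  multi_sex <- nlevels(df$sex) > 1
  form <- if (multi_age && multi_sex) glycan ~ sex * age_group
          else if (multi_sex) glycan ~ sex
          else glycan ~ age_group
  fit <- lm(form, data = df)
  contrasts <- list()
  if (multi_age && multi_sex) {
    emm <- emmeans::emmeans(fit, ~ sex * age_group)
    contrasts$age_within_sex <-
      as_tibble(summary(emmeans::contrast(emm, "pairwise", by = "sex"),
                        adjust = "none"))
    contrasts$sex_within_age <-
      as_tibble(summary(emmeans::contrast(emm, "pairwise", by = "age_group"),
                        adjust = "none"))
  } else {
    by <- NULL
    emm <- emmeans::emmeans(fit, if (multi_sex) ~sex else ~age_group)
    contrasts$pairwise <-
      as_tibble(summary(emmeans::contrast(emm, "pairwise"), adjust = "none"))
  }
  ctab <- dplyr::bind_rows(contrasts, .id = "family")
  stratum_col <- intersect(c("sex", "age_group"), names(ctab))
  ctab$stratum <- if (length(stratum_col)) {
    do.call(paste, c(lapply(stratum_col, function(cn) as.character(ctab[[cn]])),
                     sep = "/"))
  } else ""
  ctab <- dplyr::transmute(ctab,
    family = .data$family, contrast = .data$contrast, stratum = .data$stratum,
    estimate = .data$estimate, se = .data$SE, df = .data$df,
    t = .data$t.ratio, p = .data$p.value)
  ctab$q <- bh_adjust(ctab$p)
  structure(list(fit = fit, emmeans = emm, contrasts = ctab,
                 cells = cells), class = "t1d_sexage_fit")
}

#' @export
tidy.t1d_sexage_fit <- function(x, ...) x$contrasts

#' @export
glance.t1d_sexage_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = length(s$residuals), r.squared = s$r.squared,
         sigma = s$sigma, n_contrasts = nrow(x$contrasts),
         n_significant = sum(x$contrasts$q < 0.05))
}

#' @method print t1d_sexage_fit
#' @export
print.t1d_sexage_fit <- function(x, ...) {
  cat("<sex x age-group glycan model> ", nrow(x$contrasts),
      " pairwise contrasts (", sum(x$contrasts$q < 0.05),
      " with q < 0.05)\n", sep = "")
  print(x$contrasts, n = 6)
  invisible(x)
}

#' Censored autoantibody regression for one glycan
#'
#' Linear model of a rank-normalised glycan on an autoantibody level
#' subject to an upper limit of quantification:
#' `glycan = b0 + I * b1 * c + (1 - I) * b2 + sex + age`, where `I = 1`
#' when the level is below the LOQ (quantified) and `I = 0` at/above it.
#' `b1` is the per-unit effect of the quantified level and `b2` the
#' constant offset for observations beyond the LOQ. `censor_side =
#' "lower"` flips the indicator for conventional lower-LOQ assays.
#'
#' @param data Data frame holding the columns below.
#' @param glycan,level Columns (tidy-eval) with the rank-normalised glycan
#'   and the recorded level (capped at the LOQ).
#' @param loq The limit of quantification (same units as `level`).
#' @param sex,age Covariate columns; defaults to `sex` and `age`. Set to
#'   `NULL` to omit.
#' @param censor_side `"upper"` (default: levels at/above the LOQ are
#'   unquantified) or `"lower"`.
#' @return An object of class `t1d_censored_fit`; `tidy()` gives the
#'   coefficient table, `glance()` counts and fit statistics.
#' @examples
#' d <- simulate_censored_response(200, b0 = 0, b1 = 0.6, b2 = 1)
#' fit <- fit_censored_autoantibody_model(d, glycan, level, loq = max(d$level))
#' tidy(fit)
#' @export
fit_censored_autoantibody_model <- function(data, glycan, level, loq,
                                            sex = sex, age = age,
                                            censor_side = c("upper", "lower")) {
  censor_side <- match.arg(censor_side)
  y <- dplyr::pull(data, {{ glycan }})
  cc <- dplyr::pull(data, {{ level }})
  if (loq <= 0) abort("`loq` must be > 0.")
  I <- if (censor_side == "upper") cc < loq else cc > loq
  df <- tibble(y = y, slope_term = as.numeric(I) * cc,
               beyond_loq = 1 - as.numeric(I))
  covars <- character()
  sexq <- rlang::enquo(sex)
  ageq <- rlang::enquo(age)
  if (!rlang::quo_is_null(sexq)) {
    df$sex <- factor(dplyr::pull(data, !!sexq))
    covars <- c(covars, "sex")
  }
  if (!rlang::quo_is_null(ageq)) {
    df$age <- dplyr::pull(data, !!ageq)
    covars <- c(covars, "age")
  }
  n_beyond <- sum(!I)
  dropped <- character()
  terms <- c("slope_term", "beyond_loq")
  if (n_beyond == 0) {
    terms <- "slope_term"
    dropped <- "b2"
    warn("No observations beyond the LOQ: b2 dropped, model reduces to an ordinary regression on the level.")
  } else if (n_beyond == length(I)) {
    terms <- "beyond_loq"
    dropped <- "b1"
    warn("All observations beyond the LOQ: b1 not identifiable and dropped.")
  }
  form <- as.formula(paste("y ~", paste(c(terms, covars), collapse = " + ")))
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0("Collinear design: coefficients not estimable for ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  cf <- summary(fit)$coefficients
  grab <- function(nm) {
    if (nm %in% rownames(cf)) cf[nm, ] else rep(NA_real_, 4)
  }
  est <- rbind(b0 = grab("(Intercept)"), b1 = grab("slope_term"),
               b2 = grab("beyond_loq"))
  structure(list(fit = fit,
                 b0 = est["b0", 1], b1 = est["b1", 1], b2 = est["b2", 1],
                 coefficients = est,
                 n_censored = n_beyond, n_uncensored = sum(I),
                 dropped = dropped, censor_side = censor_side, loq = loq),
            class = "t1d_censored_fit")
}

#' @export
tidy.t1d_censored_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  map <- c("(Intercept)" = "b0", slope_term = "b1", beyond_loq = "b2")
  term <- rownames(cf)
  term <- ifelse(term %in% names(map), map[term], term)
  tibble(term = unname(term), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @export
glance.t1d_censored_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = x$n_censored + x$n_uncensored, n_censored = x$n_censored,
         n_uncensored = x$n_uncensored, r.squared = s$r.squared,
         sigma = s$sigma, dropped = paste(x$dropped, collapse = ","))
}

#' @method print t1d_censored_fit
#' @export
print.t1d_censored_fit <- function(x, ...) {
  cat("<censored autoantibody model> n=", x$n_censored + x$n_uncensored,
      " (", x$n_censored, " beyond LOQ)\n", sep = "")
  cat(sprintf("  b0 = %.4f  b1 = %.4f  b2 = %.4f\n", x$b0, x$b1, x$b2))
  if (length(x$dropped)) cat("  dropped:", x$dropped, "\n")
  invisible(x)
}

#' Autoantibody-count trend model for one glycan
#'
#' Linear model of a rank-normalised glycan on the number of islet
#' autoantibodies (ordered 1-4, entered as a numeric linear score),
#' adjusted for sex and age. The slope is the change in glycan SD units per
#' additional autoantibody.
#'
#' @inheritParams fit_censored_autoantibody_model
#' @param count Column with the autoantibody count (1-4).
#' @param glycan_id Label for the result row.
#' @return One-row tibble: `glycan, beta, ci_lo, ci_hi, se, p`.
#' @export
fit_autoantibody_count_model <- function(data, glycan, count,
                                         sex = sex, age = age,
                                         glycan_id = NULL) {
  glycan_id <- glycan_id %||% rlang::as_name(rlang::enquo(glycan))
  df <- tibble(y = dplyr::pull(data, {{ glycan }}),
               count = as.numeric(dplyr::pull(data, {{ count }})))
  if (dplyr::n_distinct(df$count) < 2) {
    abort("Need at least 2 distinct autoantibody counts.")
  }
  covars <- character()
  sexq <- rlang::enquo(sex); ageq <- rlang::enquo(age)
  if (!rlang::quo_is_null(sexq)) {
    df$sex <- factor(dplyr::pull(data, !!sexq)); covars <- c(covars, "sex")
  }
  if (!rlang::quo_is_null(ageq)) {
    df$age <- dplyr::pull(data, !!ageq); covars <- c(covars, "age")
  }
  fit <- lm(as.formula(paste("y ~", paste(c("count", covars), collapse = " + "))),
            data = df)
  cf <- summary(fit)$coefficients["count", ]
  ci <- stats::confint(fit)["count", ]
  tibble(glycan = glycan_id, beta = cf[1], ci_lo = ci[1], ci_hi = ci[2],
         se = cf[2], p = cf[4])
}

# Jeffreys-penalised (Firth) logistic regression, used when ordinary
# maximum likelihood separates
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    h <- rowSums((XW %*% solve(XtWX)) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- solve(XtWX, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(XtWX)))
  list(coef = setNames(beta, colnames(X)), se = setNames(se, colnames(X)))
}

disease_association_one <- function(g, status01, age, sexM, family,
                                    method = "glmm") {
  g <- standardize(g)
  df <- data.frame(y = status01, g = g, age = age, sexM = sexM,
                   family = family)
  method_used <- method
  note <- ""
  est <- se <- NA_real_
  if (method == "glmm") {
    fit <- tryCatch(
      suppressMessages(lme4::glmer(y ~ g + age + sexM + (1 | family),
                                   data = df, family = binomial,
                                   control = lme4::glmerControl(
                                     check.conv.singular =
                                       lme4::.makeCC(action = "ignore",
                                                     tol = 1e-4)))),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
      if (vc > 1e-8) {
        cf <- summary(fit)$coefficients
        est <- cf["g", 1]; se <- cf["g", 2]
      } else {
        method_used <- "glm_cluster"
        note <- "random-intercept variance degenerate"
      }
    } else {
      method_used <- "glm_cluster"
      note <- "glmm did not converge"
    }
  } else {
    method_used <- "glm_cluster"
  }
  separation <- FALSE
  if (is.na(est)) {
    fit <- suppressWarnings(glm(y ~ g + age + sexM, data = df,
                                family = binomial))
    separation <- !fit$converged || any(abs(coef(fit)) > 12)
    if (separation) {
      X <- model.matrix(~ g + age + sexM, data = df)
      fr <- firth_logistic(X, df$y)
      est <- fr$coef["g"]; se <- fr$se["g"]
      method_used <- "firth"
      note <- paste0(note, if (nzchar(note)) "; ",
                     "separation: Firth-penalised fallback")
    } else {
      V <- sandwich::vcovCL(fit, cluster = df$family)
      est <- coef(fit)["g"]; se <- sqrt(V["g", "g"])
    }
  }
  z <- est / se
  tibble(logor = est, or = exp(est),
         ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
         se = se, p = 2 * pnorm(-abs(z)),
         method = method_used, separation = separation, note = note)
}

#' Disease-status association across a glycan panel
#'
#' Per glycan: logistic regression of affected status on the standardised
#' glycan, adjusted for age and sex, with family-clustered uncertainty --
#' by default a random family intercept (lme4), falling back to a
#' cluster-robust-SE glm when the variance estimate degenerates, and to a
#' Firth-penalised fit under perfect separation. Odds ratios are per 1 SD
#' of the (rank-normalised) glycan; q-values are BH-adjusted across the
#' panel.
#'
#' @param table Peak table in state `"rank_normal"` (a percent-state trait
#'   table from [compute_derived_traits()] is also accepted; traits are
#'   standardised internally).
#' @param metadata Metadata with `sample_id, family_id, sex, age, status`
#'   (`status` coded `"affected"`/`"unaffected"` or 0/1).
#' @param glycans Columns to test; default all non-`sample_id` columns.
#' @param method `"glmm"` (default) or `"glm"` (cluster-robust only).
#' @return A tibble: `glycan, or, ci_lo, ci_hi, se, p, q, method,
#'   separation, note`, one row per glycan, in input column order.
#' @export
disease_association <- function(table, metadata, glycans = NULL,
                                method = c("glmm", "glm")) {
  method <- match.arg(method)
  metadata <- metadata[match(table$sample_id, metadata$sample_id), ]
  check_metadata_match(table, metadata)
  status01 <- status_binary(metadata$status)
  if (length(unique(status01)) < 2) {
    abort("Need both affected and unaffected samples.")
  }
  glycans <- glycans %||% setdiff(names(table), "sample_id")
  res <- purrr::map_dfr(glycans, function(gn) {
    dplyr::bind_cols(tibble(glycan = gn),
                     disease_association_one(table[[gn]], status01,
                                             metadata$age,
                                             as.numeric(metadata$sex == "M"),
                                             metadata$family_id,
                                             method = method))
  })
  res$q <- bh_adjust(res$p)
  dplyr::relocate(res, "glycan", "or", "ci_lo", "ci_hi", "se", "p", "q")
}

status_binary <- function(status) {
  if (is.numeric(status)) return(as.integer(status != 0))
  as.integer(status %in% c("affected", "case", "t1d", "1", "TRUE"))
}
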