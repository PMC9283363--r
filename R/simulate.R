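#' Configuration for the synthetic sibling-pair cohort generator
#'
#' The generator emulates a family-based case-sibling design: each family has
#' one affected proband and 0-5 unaffected siblings. Chromatogram peak areas
#' are generated multiplicatively: on the log scale each sample x peak value
#' is `baseline + family effect + batch effect + disease/sex/age terms +
#' residual`, then exponentiated. Family and batch effects are drawn per
#' (family, peak) and (batch, peak) respectively, so siblings share
#' peak-level intercepts (inducing the within-family correlation the
#' downstream clustered models assume) and batches shift each peak
#' additively on the log scale (exactly the location model the empirical
#' Bayes batch correction fits).
#'
#' @param n_families Number of families.
#' @param family_size_probs Probabilities of total family size 1..6 (one
#'   affected proband plus 0-5 unaffected siblings). The default gives about
#'   1.3 unaffected siblings per proband, matching a registry-style
#'   case-sibling cohort.
#' @param n_peaks Number of chromatogram peaks (39 for plasma, 24 for IgG by
#'   convention; any value >= 2 is accepted).
#' @param n_batches Number of plates/batches; samples are assigned
#'   round-robin in id order.
#' @param batch_shift_sd SD of the per-(batch, peak) additive log-scale shift.
#' @param family_intercept_sd SD of the per-(family, peak) random intercept.
#' @param residual_sd SD of the per-observation log-scale residual.
#' @param disease_effect,sex_effect Per-peak log-scale shifts for affected
#'   status and male sex (length `n_peaks`, recycled from a scalar).
#' @param age_slope Per-peak log-scale slope on centred age (years minus the
#'   midpoint of `age_range`), length `n_peaks`.
#' @param age_range Ages are drawn uniformly over this range (years).
#' @param baseline Per-peak baseline log-areas. The default is a smooth
#'   unimodal abundance profile so that peak percentages span roughly
#'   0.3-10%, as in real HILIC-UPLC chromatograms.
#' @param autoantibody_params Named list of per-assay parameter lists, see
#'   [simulate_autoantibodies()].
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config.
#' @return A list of class `t1d_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_families = 150,
                       family_size_probs = c(0, 0.78, 0.15, 0.04, 0.02, 0.01),
                       n_peaks = 39,
                       n_batches = 4,
                       batch_shift_sd = 0.2,
                       family_intercept_sd = 0.3,
                       residual_sd = 0.3,
                       disease_effect = 0,
                       sex_effect = 0,
                       age_slope = 0,
                       age_range = c(0.6, 19.1),
                       baseline = NULL,
                       autoantibody_params = default_autoantibody_params(),
                       seed = 1L) {
  recycle <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, n_peaks)
    if (length(v) != n_peaks) {
      abort(paste0("`", nm, "` must have length n_peaks (", n_peaks,
                   "), got ", length(v), "."))
    }
    v
  }
  if (n_families < 1) abort("`n_families` must be >= 1.")
  if (n_peaks < 2) abort("`n_peaks` must be >= 2.")
  if (length(family_size_probs) != 6 || any(family_size_probs < 0)) {
    abort("`family_size_probs` must be 6 non-negative probabilities (sizes 1..6).")
  }
  for (nm in c("batch_shift_sd", "family_intercept_sd", "residual_sd")) {
    if (get(nm) < 0) abort(paste0("`", nm, "` must be >= 0."))
  }
  if (is.null(baseline)) baseline <- default_baseline(n_peaks)
  cfg <- list(
    n_families = as.integer(n_families),
    family_size_probs = family_size_probs / sum(family_size_probs),
    n_peaks = as.integer(n_peaks),
    n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd,
    family_intercept_sd = family_intercept_sd,
    residual_sd = residual_sd,
    disease_effect = recycle(disease_effect, "disease_effect"),
    sex_effect = recycle(sex_effect, "sex_effect"),
    age_slope = recycle(age_slope, "age_slope"),
    age_range = age_range,
    baseline = recycle(baseline, "baseline"),
    autoantibody_params = autoantibody_params,
    seed = as.integer(seed)
  )
  structure(cfg, class = "t1d_sim_config")
}

# smooth unimodal log-abundance profile; peaks around the first third of the
# chromatogram dominate, late peaks are minor (typical of HILIC-UPLC runs)
default_baseline <- function(n_peaks) {
  pos <- seq_len(n_peaks)
  w <- stats::dlnorm(pos, meanlog = log(n_peaks / 3), sdlog = 0.7)
  w <- w / sum(w)
  log(1000 * (0.9 * w + 0.1 / n_peaks))
}

#' @rdname sim_config
#' @export
default_autoantibody_params <- function() {
  one <- function() list(meanlog = 0.5, sdlog = 1, loq = stats::qlnorm(0.8, 0.5, 1),
                         peak = NULL, b1 = 0, b2 = 0)
  list(znt8r = one(), znt8w = one(), gad = one(), ia2 = one())
}

#' Simulate a synthetic sibling-pair glycomics cohort
#'
#' Draws a complete cohort -- raw peak-area table plus sample metadata --
#' from the generative model described in [sim_config()]. Every sample
#' belongs to exactly one family; every family contains exactly one affected
#' proband. Sexes are Bernoulli(0.5), ages uniform over the configured
#' range, batches round-robin over plates.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `t1d_cohort` with elements `peak_table` (raw
#'   areas, strictly positive), `metadata` (`sample_id, family_id, sex, age,
#'   status, batch`), and `truth` (the generating config plus the realised
#'   family and batch effect matrices, for recovery tests).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 20, seed = 7))
#' dplyr::count(cohort$metadata, status)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "t1d_sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  set.seed(config$seed)
  nf <- config$n_families
  sizes <- sample(1:6, nf, replace = TRUE, prob = config$family_size_probs)
  n <- sum(sizes)
  family_id <- rep(sprintf("F%04d", seq_len(nf)), sizes)
  affected <- unlist(lapply(sizes, function(s) c(TRUE, rep(FALSE, s - 1))))
  sample_id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")
  age <- runif(n, config$age_range[1], config$age_range[2])
  batch <- sprintf("plate%02d", ((seq_len(n) - 1) %% config$n_batches) + 1)

  p <- config$n_peaks
  fam_eff <- matrix(rnorm(nf * p, 0, config$family_intercept_sd), nf, p,
                    dimnames = list(unique(family_id), NULL))
  batch_eff <- matrix(rnorm(config$n_batches * p, 0, config$batch_shift_sd),
                      config$n_batches, p,
                      dimnames = list(sprintf("plate%02d",
                                              seq_len(config$n_batches)), NULL))
  age_c <- age - mean(config$age_range)
  loga <- matrix(config$baseline, n, p, byrow = TRUE) +
    fam_eff[family_id, , drop = FALSE] +
    batch_eff[batch, , drop = FALSE] +
    outer(as.numeric(affected), config$disease_effect) +
    outer(as.numeric(sex == "M"), config$sex_effect) +
    outer(age_c, config$age_slope) +
    matrix(rnorm(n * p, 0, config$residual_sd), n, p)
  areas <- exp(loga)
  colnames(areas) <- paste0("GP", seq_len(p))

  pt <- peak_table(dplyr::bind_cols(tibble(sample_id = sample_id),
                                    as_tibble(areas)), state = "raw")
  md <- tibble(sample_id = sample_id, family_id = family_id, sex = sex,
               age = age, status = ifelse(affected, "affected", "unaffected"),
               batch = batch)
  structure(list(peak_table = pt, metadata = md,
                 truth = list(config = config, family_effects = fam_eff,
                              batch_effects = batch_eff)),
            class = "t1d_cohort")
}

#' @method print t1d_cohort
#' @export
print.t1d_cohort <- function(x, ...) {
  md <- x$metadata
  cat("<t1d_cohort> ", nrow(md), " samples / ",
      dplyr::n_distinct(md$family_id), " families (",
      sum(md$status == "affected"), " affected, ",
      sum(md$status == "unaffected"), " unaffected), ",
      length(peak_ids(x$peak_table)), " peaks\n", sep = "")
  invisible(x)
}

#' Add censored autoantibody measurements to a simulated cohort
#'
#' For each configured assay, affected samples receive a latent log-normal
#' autoantibody level `c`. The recorded level is `min(c, LOQ)` together with
#' the indicator `I = 1` if `c < LOQ` (below the upper limit of
#' quantification) and `I = 0` otherwise. If the assay designates a peak,
#' that peak's log-area receives `+ b1 * c` when below the LOQ and `+ b2`
#' when at/above it -- the generator inverts the censored regression model
#' that [fit_censored_autoantibody_model()] estimates, so the slope `b1` and
#' offset `b2` are recoverable downstream. Affected samples also get an
#' autoantibody count `n_autoantibodies` (1-4: the number of assays whose
#' latent level exceeds its median, floored at one).
#'
#' @param cohort A `t1d_cohort` from [simulate_cohort()].
#' @param params Named per-assay parameter list, each with `meanlog`,
#'   `sdlog`, `loq` (> 0), and optionally `peak` (a peak id), `b1`, `b2`.
#'   Defaults to the config the cohort was generated with.
#' @return The cohort with metadata columns `<assay>_level` and
#'   `<assay>_below_loq` added (NA for unaffected siblings), the peak table
#'   updated where an assay designates a peak, and latent levels recorded in
#'   `truth`.
#' @export
simulate_autoantibodies <- function(cohort, params = NULL) {
  stopifnot(inherits(cohort, "t1d_cohort"))
  params <- params %||% cohort$truth$config$autoantibody_params
  md <- cohort$metadata
  aff <- md$status == "affected"
  if (!any(aff)) abort("Cohort has no affected samples.")
  set.seed(cohort$truth$config$seed + 1L)
  m <- peak_matrix(cohort$peak_table)
  latents <- list()
  pos <- matrix(FALSE, sum(aff), length(params))
  for (k in seq_along(params)) {
    nm <- names(params)[k]
    pr <- params[[k]]
    if (pr$loq <= 0) abort(paste0("LOQ for assay '", nm, "' must be > 0."))
    cc <- rlnorm(sum(aff), pr$meanlog, pr$sdlog)
    below <- cc < pr$loq
    lvl <- pmin(cc, pr$loq)
    md[[paste0(nm, "_level")]] <- NA_real_
    md[[paste0(nm, "_level")]][aff] <- lvl
    md[[paste0(nm, "_below_loq")]] <- NA
    md[[paste0(nm, "_below_loq")]][aff] <- below
    if (!is.null(pr$peak)) {
      if (!pr$peak %in% colnames(m)) {
        abort(paste0("Designated peak '", pr$peak, "' not in the peak table."))
      }
      bump <- ifelse(below, pr$b1 * cc, pr$b2)
      m[aff, pr$peak] <- m[aff, pr$peak] * exp(bump)
    }
    latents[[nm]] <- cc
    pos[, k] <- cc > stats::qlnorm(0.5, pr$meanlog, pr$sdlog)
  }
  md$n_autoantibodies <- NA_integer_
  md$n_autoantibodies[aff] <- pmax(1L, rowSums(pos))
  cohort$metadata <- md
  cohort$peak_table <- set_peak_values(cohort$peak_table, m, "raw")
  cohort$truth$autoantibody_latent <- latents
  cohort
}

#' Draw data directly from the censored autoantibody regression model
#'
#' Generates `(glycan, level, I)` triples from
#' `glycan = b0 + I * b1 * c + (1 - I) * b2 + sex + age + noise`, with
#' `I = 1` when the latent level `c` is below the upper limit of
#' quantification and the recorded level equal to `min(c, LOQ)`. This is the
#' exact generative inverse of [fit_censored_autoantibody_model()] and is
#' what the parameter-recovery checks sample from.
#'
#' @param n Number of observations.
#' @param b0,b1,b2 Intercept, below-LOQ slope, at/above-LOQ offset.
#' @param meanlog,sdlog Latent log-normal level distribution.
#' @param loq Upper limit of quantification (> 0); default is the latent
#'   80th percentile, i.e. about 20% of observations censored.
#' @param sex_effect,age_slope Covariate effects on the glycan value.
#' @param residual_sd Residual SD of the glycan value.
#' @param age_range Uniform age range (years).
#' @return A tibble with columns `glycan`, `level` (recorded, capped at
#'   `loq`), `latent`, `below_loq`, `sex`, `age`.
#' @export
simulate_censored_response <- function(n, b0 = 0, b1 = 0.59, b2 = 0.8,
                                       meanlog = 0.5, sdlog = 1,
                                       loq = stats::qlnorm(0.8, meanlog, sdlog),
                                       sex_effect = 0.2, age_slope = 0.02,
                                       residual_sd = 1,
                                       age_range = c(0.6, 19.1)) {
  if (loq <= 0) abort("`loq` must be > 0.")
  cc <- rlnorm(n, meanlog, sdlog)
  below <- cc < loq
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")
  age <- runif(n, age_range[1], age_range[2])
  glycan <- b0 + ifelse(below, b1 * cc, b2) +
    sex_effect * (sex == "M") + age_slope * age + rnorm(n, 0, residual_sd)
  tibble(glycan = glycan, level = pmin(cc, loq), latent = cc,
         below_loq = below, sex = sex, age = age)
}
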