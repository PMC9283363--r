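#' Total-area normalisation of chromatogram peaks
#'
#' Expresses every peak as a percentage of the sample's total integrated
#' chromatogram area: `value[i, j] = 100 * area[i, j] / sum_j area[i, j]`.
#'
#' @param table A peak table in state `"raw"` (non-negative areas).
#' @return A peak table in state `"percent"`; each row sums to 100 within
#'   1e-9.
#' @examples
#' pt <- peak_table(tibble::tibble(sample_id = "a", GP1 = 1, GP2 = 3))
#' normalize_total_area(pt)
#' @export
normalize_total_area <- function(table) {
  require_state(table, "raw", "normalize_total_area")
  m <- peak_matrix(table)
  if (any(m < 0)) abort("Raw areas must be non-negative.")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("Samples with zero total area: ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  set_peak_values(table, 100 * m / tot, "percent")
}

#' Log-transform peak percentages
#'
#' Natural log, applied elementwise. Exact zeros are handled by
#' `zero_policy`: the default replaces zeros in a peak column with half the
#' smallest positive value observed for that peak before logging
#' (chromatogram peaks are rarely exactly zero, so this touches few cells).
#'
#' @param table A peak table in state `"percent"`.
#' @param zero_policy `"half_min"` (default) or `"error"`.
#' @return A peak table in state `"log"`.
#' @export
log_transform <- function(table, zero_policy = c("half_min", "error")) {
  require_state(table, "percent", "log_transform")
  zero_policy <- match.arg(zero_policy)
  m <- peak_matrix(table)
  if (any(m < 0)) abort("Percentages must be non-negative.")
  if (any(m == 0)) {
    if (zero_policy == "error") abort("Zero percentages present.")
    for (j in seq_len(ncol(m))) {
      z <- m[, j] == 0
      if (any(z)) {
        pos <- m[!z, j]
        if (!length(pos)) abort(paste0("Peak ", colnames(m)[j],
                                       " is zero for every sample."))
        m[z, j] <- min(pos) / 2
      }
    }
  }
  set_peak_values(table, log(m), "log")
}

#' Empirical Bayes batch correction (ComBat)
#'
#' Removes additive/multiplicative plate effects from log-scale peak values
#' using the parametric empirical Bayes location/scale model: per-peak
#' standardisation, per-batch shrinkage of the additive and multiplicative
#' batch parameters toward batch-level hyperpriors, adjustment and
#' back-transformation. The computation is delegated to [sva::ComBat()]
#' (parametric prior, no covariate model matrix, no reference batch).
#'
#' @param table A peak table in state `"log"`.
#' @param batch Batch labels, one per sample (character/factor), or the name
#'   of a column in `metadata`.
#' @param metadata Optional metadata tibble carrying the batch column.
#' @return A peak table in state `"batch_corrected"`. With a single batch
#'   the input values are returned unchanged (with a warning), state
#'   advanced.
#' @export
combat_correct <- function(table, batch, metadata = NULL) {
  require_state(table, "log", "combat_correct")
  if (is.character(batch) && length(batch) == 1 && !is.null(metadata)) {
    check_metadata_match(table, metadata)
    batch <- metadata[[batch]][match(table$sample_id, metadata$sample_id)]
  }
  batch <- as.character(batch)
  if (length(batch) != nrow(table)) {
    abort("`batch` must supply one label per sample.")
  }
  counts <- table(batch)
  if (any(counts < 2)) {
    abort(paste0("Every batch needs >= 2 samples; too small: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  m <- peak_matrix(table)
  if (length(counts) < 2) {
    warn("Single batch: returning values unchanged.")
    return(set_peak_values(table, m, "batch_corrected"))
  }
  # sva works on features x samples; capture its console chatter
  out <- utils::capture.output(
    corrected <- suppressMessages(
      sva::ComBat(dat = t(m), batch = factor(batch),
                  par.prior = TRUE, prior.plots = FALSE)))
  set_peak_values(table, t(corrected), "batch_corrected")
}

#' Rank-based inverse normal transformation
#'
#' Maps values through `qnorm((rank - 0.5) / n)` using average ranks for
#' ties, then re-centres and rescales to mean 0, SD 1. The transform is
#' monotone in the input and forces marginal normality; it is applied to
#' each peak before any statistical modelling.
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @return Numeric vector with mean 0 and SD 1 (within 1e-12).
#' @examples
#' rank_inverse_normal(c(3, 1, 4, 1, 5))
#' @export
rank_inverse_normal <- function(x) {
  if (length(x) < 2) abort("Need at least 2 values.")
  if (anyNA(x)) abort("Missing values are not supported.")
  if (diff(range(x)) == 0) {
    abort("Constant vector: ranks are undefined up to ties covering all entries.")
  }
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 0.5) / length(x))
  (z - mean(z)) / sd(z)
}

#' @rdname rank_inverse_normal
#' @param table A peak table in state `"batch_corrected"` (or `"log"` /
#'   `"percent"` for unbatched designs).
#' @return `rank_normalize()` returns a peak table in state `"rank_normal"`
#'   with every peak transformed column-wise.
#' @export
rank_normalize <- function(table) {
  require_state(table, c("batch_corrected", "log", "percent"), "rank_normalize")
  m <- peak_matrix(table)
  set_peak_values(table, apply(m, 2, rank_inverse_normal), "rank_normal")
}

#' Run the full preprocessing chain
#'
#' Fixed order: total-area normalisation, log transform, empirical Bayes
#' batch correction, rank-based inverse normal transformation. Stop early
#' with `until`.
#'
#' @param table A peak table in state `"raw"`.
#' @param metadata Metadata tibble with a `batch` column.
#' @param until Final state, one of `"percent"`, `"log"`,
#'   `"batch_corrected"`, `"rank_normal"` (default).
#' @inheritParams log_transform
#' @return A peak table in the requested state.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 20, seed = 1))
#' pt <- preprocess_peaks(cohort$peak_table, cohort$metadata, until = "percent")
#' @export
preprocess_peaks <- function(table, metadata, until = "rank_normal",
                             zero_policy = "half_min") {
  until <- match.arg(until, c("percent", "log", "batch_corrected", "rank_normal"))
  out <- normalize_total_area(table)
  if (until == "percent") return(out)
  out <- log_transform(out, zero_policy = zero_policy)
  if (until == "log") return(out)
  out <- combat_correct(out, "batch", metadata)
  if (until == "batch_corrected") return(out)
  rank_normalize(out)
}
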