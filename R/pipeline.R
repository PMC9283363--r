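# derive a per-stage seed from the global seed so every stage is
# reproducible independently of execution order
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 2654435761 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> derived traits ->
#' disease association -> discrimination, writing versioned stage outputs,
#' a `manifest.json` (input hashes, seeds, package version) and a markdown
#' summary into an output directory. Stages are reproducible: one global
#' seed is fanned out into per-stage seeds.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{peaks, metadata}{Paths to input TSVs, or omit both and supply
#'       `simulate` (a list of [sim_config()] arguments) to generate a
#'       cohort.}
#'     \item{schema}{`"plasma"` (default) or `"igg"`.}
#'     \item{out_dir}{Output directory (created).}
#'     \item{seed}{Global integer seed (default 1).}
#'     \item{stages}{Character subset of
#'       `c("preprocess", "traits", "associate", "discriminate")`; default all.}
#'     \item{discriminate}{Optional list of [run_full_vs_null()] arguments
#'       (`alpha`, `lambda`, `k`, `n_boot`, `random_effect`).}
#'   }
#' @return The output directory path, invisibly; the manifest is returned as
#'   the `"manifest"` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% abort("`out_dir` is required.")
  seed <- as.integer(config$seed %||% 1L)
  schema <- config$schema %||% "plasma"
  stages <- config$stages %||% c("preprocess", "traits", "associate",
                                 "discriminate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("t1dglyco")),
                   seed = seed, schema = schema, stages = stages,
                   inputs = list(), outputs = list())
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
    inform(paste0(...))
  }

  if (!is.null(config$peaks)) {
    for (f in c(config$peaks, config$metadata)) {
      if (!file.exists(f)) abort(paste0("Input file does not exist: ", f))
    }
    peaks <- read_peak_table(config$peaks, state = "raw")
    metadata <- read_sample_metadata(config$metadata)
    manifest$inputs <- list(peaks = unname(tools::md5sum(config$peaks)),
                            metadata = unname(tools::md5sum(config$metadata)))
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% stage_seed(seed, "simulate")
    cohort <- simulate_cohort(do.call(sim_config, sim_args))
    peaks <- cohort$peak_table
    metadata <- cohort$metadata
    write_peak_table(peaks, file.path(out_dir, "peaks.tsv"))
    readr::write_tsv(metadata, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(cohort$truth$config[
      c("n_families", "n_peaks", "n_batches", "batch_shift_sd",
        "family_intercept_sd", "residual_sd", "seed")],
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    manifest$inputs <- list(simulated = TRUE, sim_seed = sim_args$seed)
    log_line("simulate: ", nrow(metadata), " samples written")
  } else {
    abort("Config needs either `peaks` + `metadata` paths or a `simulate` block.")
  }

  if ("preprocess" %in% stages) {
    pct <- preprocess_peaks(peaks, metadata, until = "percent")
    rn <- rank_normalize(combat_correct(log_transform(pct), "batch", metadata))
    write_peak_table(rn, file.path(out_dir, "normalized.tsv"))
    log_line("preprocess: normalized table written")
  } else {
    abort("The preprocess stage cannot be skipped: downstream stages need it.")
  }

  if ("traits" %in% stages) {
    traits <- compute_derived_traits(pct, schema)
    readr::write_tsv(traits, file.path(out_dir, "traits.tsv"))
    log_line("traits: ", ncol(traits) - 1, " derived traits written")
  }

  assoc <- NULL
  if ("associate" %in% stages) {
    assoc <- disease_association(rn, metadata)
    readr::write_tsv(assoc, file.path(out_dir, "disease_association.tsv"))
    log_line("associate: ", sum(assoc$q < 0.05), " glycans with q < 0.05")
  }

  disc <- NULL
  if ("discriminate" %in% stages) {
    dargs <- config$discriminate %||% list()
    disc <- run_full_vs_null(rn, metadata,
                             alpha = dargs$alpha %||% 0.1,
                             lambda = dargs$lambda %||% 1e-4,
                             k = dargs$k %||% 10,
                             n_boot = dargs$n_boot %||% 2000,
                             seed = stage_seed(seed, "discriminate"),
                             random_effect = dargs$random_effect %||% TRUE)
    jsonlite::write_json(glance(disc), file.path(out_dir, "discrimination.json"),
                         auto_unbox = FALSE, digits = NA, dataframe = "columns")
    readr::write_tsv(disc$roc_full$curve, file.path(out_dir, "roc_full.tsv"))
    readr::write_tsv(disc$roc_null$curve, file.path(out_dir, "roc_null.tsv"))
    log_line("discriminate: full AUC ", round(disc$roc_full$auc, 3),
             ", null AUC ", round(disc$roc_null$auc, 3))
  }

  summary_md <- c(
    "# Pipeline summary", "",
    paste0("- samples: ", nrow(metadata), " (",
           sum(status_binary(metadata$status)), " affected)"),
    paste0("- schema: ", schema),
    paste0("- seed: ", seed), "")
  if (!is.null(assoc)) {
    top <- dplyr::arrange(assoc, .data$p)
    summary_md <- c(summary_md, "## Disease association (top 10 by p)", "",
                    utils::capture.output(print(as.data.frame(
                      utils::head(top[, c("glycan", "or", "ci_lo", "ci_hi",
                                          "se", "p", "q")], 10))), ""))
  }
  if (!is.null(disc)) {
    summary_md <- c(summary_md, "## Discrimination", "",
                    paste0("- full AUC: ", round(disc$roc_full$auc, 3)),
                    paste0("- null AUC: ", round(disc$roc_null$auc, 3)),
                    paste0("- delta: ", round(disc$comparison$delta, 3),
                           " [", round(disc$comparison$ci[1], 3), ", ",
                           round(disc$comparison$ci[2], 3), "]"),
                    paste0("- bootstrap p: ",
                           format(disc$comparison$p, digits = 3)), "")
  }
  writeLines(summary_md, file.path(out_dir, "summary.md"))

  outs <- setdiff(list.files(out_dir), c("manifest.json", "pipeline.log"))
  manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, outs)))
  names(manifest$outputs) <- outs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(out_dir, "manifest") <- manifest
  invisible(out_dir)
}
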