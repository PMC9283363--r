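#' Load and validate a peak structural annotation
#'
#' An annotation assigns each chromatogram peak the structural features of
#' its dominant glycan: galactose and sialic acid counts, bisecting GlcNAc,
#' core and antennary fucosylation, branching class (biantennary `low`
#' vs tri-/tetra-antennary `high`) and the high-mannose flag. The shipped
#' defaults (`"plasma"`: 39 peaks, `"igg"`: 24 peaks) are synthetic panels
#' reconstructed from the published structure names for these
#' chromatographic methods; peaks with co-eluting structures carry the
#' dominant structure. Both files are plain TSV under
#' `system.file("extdata", package = "t1dglyco")` and can be edited and
#' reloaded.
#'
#' @param source `"plasma"`, `"igg"`, a file path to an annotation TSV, or a
#'   data frame with columns `peak, structure, galactose_count,
#'   sialic_count, bisecting, core_fucose, antennary_fucose, branching,
#'   high_mannose`.
#' @return A tibble of class `t1d_annotation` with logical flag columns.
#' @examples
#' ann <- load_peak_annotation("igg")
#' nrow(ann)
#' @export
load_peak_annotation <- function(source = c("plasma", "igg")) {
  if (is.data.frame(source)) {
    x <- as_tibble(source)
  } else {
    source <- as.character(source)[1]
    if (source %in% c("plasma", "igg")) {
      path <- system.file("extdata", paste0(source, "_peaks.tsv"),
                          package = "t1dglyco", mustWork = TRUE)
    } else {
      path <- source
    }
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  needed <- c("peak", "structure", "galactose_count", "sialic_count",
              "bisecting", "core_fucose", "antennary_fucose", "branching",
              "high_mannose")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("Annotation is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  for (fl in c("bisecting", "core_fucose", "antennary_fucose", "high_mannose")) {
    x[[fl]] <- as.logical(x[[fl]])
  }
  problems <- character()
  if (anyDuplicated(x$peak)) problems <- c(problems, "duplicate peak ids")
  bad_branch <- which(!x$branching %in% c("low", "high"))
  if (length(bad_branch)) {
    problems <- c(problems, paste0("unknown branching code in rows: ",
                                   paste(bad_branch, collapse = ", ")))
  }
  bad_counts <- which(x$galactose_count < 0 | x$galactose_count > 4 |
                        x$sialic_count < 0 | x$sialic_count > 4)
  if (length(bad_counts)) {
    problems <- c(problems, paste0("galactose/sialic counts outside 0..4 in rows: ",
                                   paste(bad_counts, collapse = ", ")))
  }
  # a high-mannose glycan carries only mannoses: no galactose, sialic acid or fucose
  bad_hm <- which(x$high_mannose &
                    (x$galactose_count > 0 | x$sialic_count > 0 |
                       x$bisecting | x$core_fucose | x$antennary_fucose))
  if (length(bad_hm)) {
    problems <- c(problems, paste0("high-mannose rows with complex features: ",
                                   paste(bad_hm, collapse = ", ")))
  }
  # sialic acids attach to galactoses on complex structures
  bad_s <- which(!x$high_mannose & x$sialic_count > x$galactose_count)
  if (length(bad_s)) {
    problems <- c(problems, paste0("sialic_count > galactose_count in rows: ",
                                   paste(bad_s, collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("Invalid peak annotation: ", paste(problems, collapse = "; ")))
  }
  structure(x, class = c("t1d_annotation", class(x)))
}

#' Trait names for each panel
#'
#' The 15 plasma derived traits and 9 IgG derived traits summarise shared
#' structural features: galactosylation degree (G0-G4), sialylation degree
#' (S0-S4), bisecting GlcNAc (B), antennary/core fucosylation (AF/CF),
#' branching (LB biantennary, HB tri-/tetra-antennary) and high-mannose
#' content (HM).
#'
#' @param kind `"plasma"` or `"igg"`.
#' @return Character vector of trait names.
#' @export
trait_names <- function(kind = c("plasma", "igg")) {
  kind <- match.arg(kind)
  if (kind == "plasma") {
    c("G0", "G1", "G2", "G3", "G4", "S1", "S2", "S3", "S4",
      "B", "AF", "CF", "LB", "HB", "HM")
  } else {
    c("G0", "G1", "G2", "S0", "S1", "S2", "B", "CF", "HM")
  }
}

# peaks carrying each feature; galactose/sialylation degrees are defined on
# complex (non-high-mannose) structures only
trait_membership <- function(annotation, traits) {
  cx <- !annotation$high_mannose
  member <- function(trait) {
    keep <- switch(trait,
      G0 = cx & annotation$galactose_count == 0,
      G1 = cx & annotation$galactose_count == 1,
      G2 = cx & annotation$galactose_count == 2,
      G3 = cx & annotation$galactose_count == 3,
      G4 = cx & annotation$galactose_count == 4,
      S0 = cx & annotation$sialic_count == 0,
      S1 = cx & annotation$sialic_count == 1,
      S2 = cx & annotation$sialic_count == 2,
      S3 = cx & annotation$sialic_count == 3,
      S4 = cx & annotation$sialic_count == 4,
      B  = cx & annotation$bisecting,
      AF = cx & annotation$antennary_fucose,
      CF = cx & annotation$core_fucose,
      LB = cx & annotation$branching == "low",
      HB = cx & annotation$branching == "high",
      HM = annotation$high_mannose,
      abort(paste0("Unknown trait: ", trait))
    )
    annotation$peak[keep]
  }
  setNames(lapply(traits, member), traits)
}

#' Compute derived glycosylation traits
#'
#' Each trait is the plain sum of the percentages of the peaks carrying the
#' trait's structural feature (so traits are linear in peak percentages).
#' Traits are computed on the percent-state table: derived traits summarise
#' the composition, not the rank-normalised values used for modelling.
#'
#' @param table A peak table in state `"percent"` whose peaks match the
#'   annotation exactly.
#' @param annotation A [load_peak_annotation()] result, or `"plasma"`/`"igg"`.
#' @param traits Trait names to compute; defaults to the panel's full set
#'   (15 plasma / 9 IgG, inferred from the peak count when `annotation` is a
#'   shipped panel name, else all derivable traits).
#' @return A tibble: `sample_id` plus one column per trait, values in
#'   `[0, 100]`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 10, n_peaks = 39))
#' pct <- normalize_total_area(cohort$peak_table)
#' compute_derived_traits(pct, "plasma")
#' @export
compute_derived_traits <- function(table, annotation, traits = NULL) {
  require_state(table, "percent", "compute_derived_traits")
  if (is.character(annotation)) {
    kind <- match.arg(annotation, c("plasma", "igg"))
    annotation <- load_peak_annotation(kind)
    traits <- traits %||% trait_names(kind)
  }
  if (is.null(traits)) {
    traits <- union(trait_names("plasma"), trait_names("igg"))
    traits <- traits[lengths(trait_membership(annotation, traits)) > 0]
  }
  pk <- peak_ids(table)
  if (!setequal(pk, annotation$peak)) {
    d1 <- setdiff(pk, annotation$peak)
    d2 <- setdiff(annotation$peak, pk)
    abort(paste0("Peak mismatch between table and annotation.",
                 if (length(d1)) paste0(" Only in table: ",
                                        paste(d1, collapse = ", ")),
                 if (length(d2)) paste0(" Only in annotation: ",
                                        paste(d2, collapse = ", "))))
  }
  m <- peak_matrix(table)
  members <- trait_membership(annotation, traits)
  vals <- vapply(members,
                 function(pks) if (length(pks)) rowSums(m[, pks, drop = FALSE])
                               else rep(0, nrow(m)),
                 numeric(nrow(m)))
  if (nrow(m) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, traits))
  dplyr::bind_cols(tibble(sample_id = table$sample_id), as_tibble(vals))
}

#' Validate an annotation against the expected panel shape
#'
#' Checks the peak count and the number of derivable traits (trait names of
#' the panel with at least one member peak) against the expected panel:
#' plasma 39 peaks / 15 traits, IgG 24 peaks / 9 traits.
#'
#' @param annotation A [load_peak_annotation()] result.
#' @param expected_kind `"plasma"` or `"igg"`.
#' @return A list with `n_peaks`, `n_traits`, `expected_peaks`,
#'   `expected_traits`, per-check pass flags and overall `pass`.
#' @export
validate_schema <- function(annotation, expected_kind = c("plasma", "igg")) {
  expected_kind <- match.arg(expected_kind)
  expected <- if (expected_kind == "plasma") c(peaks = 39L, traits = 15L)
              else c(peaks = 24L, traits = 9L)
  members <- trait_membership(annotation, trait_names(expected_kind))
  n_traits <- sum(lengths(members) > 0)
  res <- list(
    kind = expected_kind,
    n_peaks = nrow(annotation),
    n_traits = n_traits,
    expected_peaks = unname(expected["peaks"]),
    expected_traits = unname(expected["traits"]),
    peaks_ok = nrow(annotation) == expected["peaks"],
    traits_ok = n_traits == expected["traits"],
    empty_traits = names(members)[lengths(members) == 0]
  )
  res$pass <- res$peaks_ok && res$traits_ok
  structure(res, class = "t1d_schema_report")
}

#' @method print t1d_schema_report
#' @export
print.t1d_schema_report <- function(x, ...) {
  cat("<schema report> kind=", x$kind,
      "  peaks ", x$n_peaks, "/", x$expected_peaks,
      if (x$peaks_ok) " ok" else " FAIL",
      "  traits ", x$n_traits, "/", x$expected_traits,
      if (x$traits_ok) " ok" else " FAIL", "\n", sep = "")
  if (length(x$empty_traits)) {
    cat("  traits with no member peaks: ",
        paste(x$empty_traits, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
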