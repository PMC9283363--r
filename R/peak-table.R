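#' Peak tables and their processing state
#'
#' A peak table is a tibble with a `sample_id` column followed by one numeric
#' column per chromatogram peak (`GP1`, `GP2`, ...). The table carries a
#' processing-state flag recording where it sits in the fixed preprocessing
#' order `raw -> percent -> log -> batch_corrected -> rank_normal`; each
#' preprocessing step checks the state of its input and stamps its output.
#'
#' @param x A data frame with a `sample_id` column and numeric peak columns.
#' @param state Processing state, one of `"raw"`, `"percent"`, `"log"`,
#'   `"batch_corrected"`, `"rank_normal"`.
#' @return `peak_table()` returns the validated tibble with the state stamped
#'   in the `"glyco_state"` attribute; `peak_state()` returns that flag.
#' @examples
#' pt <- peak_table(tibble::tibble(sample_id = c("a", "b"),
#'                                 GP1 = c(1, 2), GP2 = c(3, 4)))
#' peak_state(pt)
#' @export
peak_table <- function(x, state = "raw") {
  state <- match.arg(state, peak_states())
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("A peak table needs a `sample_id` column.")
  }
  x <- dplyr::relocate(x, "sample_id")
  ids <- as.character(x$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  peaks <- setdiff(names(x), "sample_id")
  if (length(peaks) < 2) abort("A peak table needs at least 2 peak columns.")
  if (anyDuplicated(peaks)) abort("Duplicate peak ids.")
  bad <- peaks[!vapply(x[peaks], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric peak columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(x[peaks])
  if (state %in% c("raw", "percent") && any(m < 0, na.rm = TRUE)) {
    abort(paste0("State '", state, "' requires non-negative values."))
  }
  if (state == "percent") {
    rs <- rowSums(m)
    if (any(abs(rs - 100) > 1e-9)) {
      abort("State 'percent' requires each row to sum to 100 (within 1e-9).")
    }
  }
  attr(x, "glyco_state") <- state
  x
}

peak_states <- function() {
  c("raw", "percent", "log", "batch_corrected", "rank_normal")
}

#' @rdname peak_table
#' @export
peak_state <- function(x) {
  attr(x, "glyco_state") %||% NA_character_
}

#' Peak id columns of a peak table
#' @param x A peak table.
#' @return Character vector of peak column names, in order.
#' @export
peak_ids <- function(x) setdiff(names(x), "sample_id")

# numeric matrix view (samples x peaks, rownames = sample ids)
peak_matrix <- function(x) {
  m <- as.matrix(x[peak_ids(x)])
  rownames(m) <- as.character(x$sample_id)
  m
}

# rebuild a peak table from a matrix, keeping sample order and state
set_peak_values <- function(x, m, state) {
  out <- dplyr::bind_cols(tibble(sample_id = x$sample_id), as_tibble(m))
  peak_table(out, state = state)
}

require_state <- function(x, expected, op) {
  st <- peak_state(x)
  if (is.na(st) || !st %in% expected) {
    abort(paste0(op, "() expects a peak table in state ",
                 paste(sQuote(expected), collapse = " or "),
                 ", got ", sQuote(st %||% "unknown"),
                 ". The pipeline order is raw -> percent -> log -> ",
                 "batch_corrected -> rank_normal."))
  }
  invisible(x)
}

#' Read / write peak tables and sample metadata
#'
#' Peak tables are TSV/CSV files whose first column is the sample id and the
#' remaining columns are peaks `GP1..GPn`; metadata files carry
#' `sample_id, family_id, sex, age, status, batch` (plus optional
#' autoantibody columns).
#'
#' @param path File path. The delimiter is inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @param state Processing state to stamp on the table read.
#' @name glyco_io
NULL

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' @rdname glyco_io
#' @return `read_peak_table()` a peak table; `read_sample_metadata()` a tibble.
#' @export
read_peak_table <- function(path, state = "raw") {
  x <- read_delim_auto(path)
  names(x)[1] <- "sample_id"
  peak_table(x, state = state)
}

#' @rdname glyco_io
#' @export
read_sample_metadata <- function(path) {
  x <- read_delim_auto(path)
  needed <- c("sample_id", "family_id", "sex", "age", "status", "batch")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("Metadata is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  x$family_id <- as.character(x$family_id)
  x
}

#' @rdname glyco_io
#' @param x Table to write.
#' @export
write_peak_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

check_metadata_match <- function(table, metadata) {
  if (!setequal(table$sample_id, metadata$sample_id)) {
    d1 <- setdiff(table$sample_id, metadata$sample_id)
    d2 <- setdiff(metadata$sample_id, table$sample_id)
    abort(paste0("Peak table and metadata sample ids differ.",
                 if (length(d1)) paste0(" Only in peaks: ",
                                        paste(head(d1, 5), collapse = ", ")),
                 if (length(d2)) paste0(" Only in metadata: ",
                                        paste(head(d2, 5), collapse = ", "))))
  }
  invisible(TRUE)
}
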