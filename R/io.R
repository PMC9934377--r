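#' Read and write the long event table
#'
#' The on-disk dialect is a delimited text file with header
#' `patient_id,date,code_type,code,value_flag`: `date` is ISO-8601,
#' `code_type` is one of `DX`, `RX`, `LAB`, and `value_flag` is empty except
#' for `LAB` rows, where it is one of `L`, `N`, `H`. `write_event_table()`
#' followed by `read_event_table()` is an identity on well-formed tables.
#'
#' @param events An event table (tibble with the five columns above).
#' @param path File path; a `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `read_event_table()` returns the validated event tibble;
#'   `write_event_table()` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  events <- validate_event_table(events, source = "events")
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(events, path, delim = delim, na = "")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- readr::read_delim(
    path, delim = delim, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      code_type = readr::col_character(),
      code = readr::col_character(),
      value_flag = readr::col_character()
    )
  )
  expected <- c("patient_id", "date", "code_type", "code", "value_flag")
  if (!identical(names(x), expected)) {
    stop("malformed event table header: expected ",
         paste(expected, collapse = ","), ", got ",
         paste(names(x), collapse = ","))
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("malformed event table at line ", prob$row[1] + 1L,
         " (file row incl. header), column ", prob$col[1], ": expected ",
         prob$expected[1])
  }
  validate_event_table(x, source = path)
}

# Shared row-level validation; errors name the offending row and column.
validate_event_table <- function(x, source = "events") {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  bad <- function(rows, col, why) {
    if (any(rows)) {
      stop("malformed event table (", source, "), data row ", which(rows)[1],
           ", column ", col, ": ", why)
    }
  }
  bad(is.na(x$patient_id) | x$patient_id == "", "patient_id", "missing id")
  bad(is.na(x$date), "date", "missing or unparseable ISO-8601 date")
  bad(!x$code_type %in% c("DX", "RX", "LAB"), "code_type",
      "must be one of DX, RX, LAB")
  bad(is.na(x$code) | x$code == "", "code", "missing code")
  flag <- x$value_flag
  bad(x$code_type == "LAB" & !flag %in% c("L", "N", "H"), "value_flag",
      "LAB rows need a flag in {L, N, H}")
  bad(x$code_type != "LAB" & !is.na(flag), "value_flag",
      "non-LAB rows must have an empty flag")
  x
}

#' Export and import the per-patient cohort label table
#'
#' Columns: `patient_id,is_case,first_event_date,first_marker_date,included,`
#' `exclusion_reason[,arm]`; dates ISO-8601, empty when absent.
#'
#' @param labels A cohort label tibble (see [find_cases()]).
#' @param path File path (CSV).
#' @export
write_cohort_labels <- function(labels, path) {
  readr::write_csv(labels, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_labels
#' @export
read_cohort_labels <- function(path) {
  readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      is_case = readr::col_logical(),
      first_event_date = readr::col_date(format = "%Y-%m-%d"),
      first_marker_date = readr::col_date(format = "%Y-%m-%d"),
      included = readr::col_logical(),
      exclusion_reason = readr::col_character(),
      .default = readr::col_character()
    )
  )
}

#' Export the per-patient truth table of a simulated cohort
#'
#' @param truth The `truth` tibble from [simulate_cohort()].
#' @param path File path (CSV).
#' @export
write_truth_table <- function(truth, path) {
  readr::write_csv(truth, path, na = "")
  invisible(path)
}
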