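# CSV dialects for the workflow tables. Plain CSV with header rows;
# units are embedded in column names.

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s file is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read workflow CSV tables
#'
#' Readers for the tidy CSV dialects the workflow exchanges: titration
#' series, standard-addition sets, nucleotide panels and glycan peak
#' tables. Each validates the expected header.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @name workflow-io
#' @export
read_titration_csv <- function(path) {
  check_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                c("analyte", "digitonin_ug_per_ml", "fraction",
                  "replicate", "amount_amol_per_cell"), "titration")
}

#' @rdname workflow-io
#' @export
read_standard_addition_csv <- function(path) {
  check_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                c("analyte", "sample_id", "spike_nM", "peak_area"),
                "standard-addition")
}

#' @rdname workflow-io
#' @export
read_nucleotide_panel_csv <- function(path) {
  check_columns(utils::read.csv(path, stringsAsFactors = FALSE),
                c("base", "ntp", "ndp", "nmp"), "nucleotide panel")
}

#' @rdname workflow-io
#' @export
read_glycan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sample_id", "species", "abundance") %in% names(df)) ||
      all(c("sample_id", "rt_min", "area") %in% names(df)))
    return(df)
  stop("glycan file must have columns sample_id,species,abundance ",
       "or sample_id,rt_min,area", call. = FALSE)
}

#' @rdname workflow-io
#' @param df Table to write.
#' @export
write_workflow_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
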