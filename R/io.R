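require_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df))
    stop(what, " must be a data frame", call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Read a pipeline table
#'
#' Comma-delimited UTF-8 text with a header row, decimal point '.', missing
#' values as "NA". When `required` is given the header is validated and a
#' missing column is reported by name.
#'
#' @param path File path.
#' @param required Optional character vector of required column names.
#' @return A data frame.
#' @export
read_frost_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(required)) require_columns(df, required, basename(path))
  df
}

#' Write a pipeline table
#'
#' Comma-delimited UTF-8 text with a header row and "NA" for missing values.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_frost_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}
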