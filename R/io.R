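# deterministic serialization: RFC-4180 CSV with 17-significant-digit
# floats (lossless double round-trip) and stable JSON

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else if (is.logical(x) || is.integer(x)) {
    as.character(x)
  } else {
    x <- as.character(x)
    needs_quote <- grepl('[",\n]', x)
    x[needs_quote] <- paste0('"', gsub('"', '""', x[needs_quote]), '"')
    x
  }
}

#' Write a result table as deterministic CSV
#'
#' RFC-4180 CSV with `.` decimal separator and 17-significant-digit
#' floats, so doubles round-trip losslessly and repeated runs produce
#' byte-identical files.
#'
#' @param df A data frame (gain curve, sweep, cycle trace, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gain_csv <- function(df, path) {
  stopifnot(is.data.frame(df))
  cols <- lapply(df, fmt_cell)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df) > 0) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write a result object as JSON
#'
#' Scalars are written as bare JSON numbers at full precision
#' (`auto_unbox = TRUE`, `digits = NA`).
#'
#' @param x A list, one-row tibble or similar.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gain_json <- function(x, path) {
  if (is.data.frame(x) && nrow(x) == 1L) x <- as.list(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
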