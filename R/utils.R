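`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a data frame as plain TSV
#'
#' UTF-8, tab-delimited, '.' decimal, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plain TSV into a data frame
#'
#' @param path input path.
#' @param ... passed to [utils::read.delim()].
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

stop_usage <- function(...) stop(sprintf(...), call. = FALSE)

# md5 of an arbitrary R object via its serialized JSON form
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
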