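# Internal helpers shared across modules: typed conditions, logging, TSV IO.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_catego <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "catego_error")))
}

#' @noRd
format_error <- function(msg) stop_catego(msg, "catego_format_error")
data_error <- function(msg) stop_catego(msg, "catego_data_error")
usage_error <- function(msg) stop_catego(msg, "catego_usage_error")

catego_log <- function(...) {
  if (isTRUE(getOption("catego.verbose", FALSE))) {
    message("[catego] ", ...)
  }
  invisible(NULL)
}

catego_warn <- function(...) {
  warning(warningCondition(paste0(...), class = "catego_warning"), call. = FALSE)
}

# Open a text connection; gzfile() transparently reads both plain and
# gzip-compressed files, which is how all readers accept .gz input.
open_text <- function(path) {
  if (inherits(path, "connection")) return(path)
  gzfile(path, open = "rt")
}

read_text_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

# Deterministic TSV writer: no quoting, "NA" sentinel, fixed EOLs.
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Read a plain gene list (one identifier per line)
#'
#' Lines are whitespace-trimmed; empty lines and `#` comments are skipped.
#' Duplicate identifiers collapse to one.
#'
#' @param path Path to a text file (optionally gzip-compressed).
#' @return Character vector of unique gene identifiers, input order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

# Format a numeric column reproducibly for TSV export.
num_chr <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "g"), x))
}
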