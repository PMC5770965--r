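#' Write a delimited table with a '#' metadata header
#'
#' Tab-separated text with metadata lines `# key: value` before the
#' header row; the format every pipeline stage reads and writes.
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named list of metadata values.
#' @export
write_table_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a delimited table written by [write_table_meta()]
#'
#' @param path input file.
#' @return data.frame with the parsed metadata in attribute `meta`.
#' @export
read_table_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    i <- regexpr(":", kv, fixed = TRUE)
    if (i > 0)
      meta[[trimws(substr(kv, 1, i - 1))]] <- trimws(substring(kv, i + 1))
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
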