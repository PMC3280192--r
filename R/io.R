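#' Write a table as tab-separated text with a metadata header
#'
#' Every pipeline output begins with commented metadata lines
#' (`# key: value`) recording at least the tool version, the RNG seed and
#' the thresholds used, so any file can be traced back to its run.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_with_meta <- function(df, path, meta = list()) {
  meta <- c(list(tool = paste0("carrierscreen ",
                               as.character(utils::packageVersion("carrierscreen")))),
            meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by this package
#'
#' @param path file path.
#' @return A tibble; commented metadata lines are parsed into the
#'   `metadata` attribute.
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "metadata") <- meta
  out
}
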