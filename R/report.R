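# Report TSVs carry a `#`-prefixed metadata preamble (version, seed,
# parameters) so every number in a report is reproducible from its header.

#' Write a report data frame as TSV with a metadata preamble
#'
#' @param df data frame.
#' @param path output path.
#' @param params named list of parameters to record (seed among them).
#' @return the path, invisibly.
#' @export
write_report_tsv <- function(df, path, params = list()) {
  meta <- c(sprintf("# eccdnaCharter %s",
                    as.character(packageVersion("eccdnaCharter"))),
            vapply(names(params), function(k) {
              sprintf("# %s: %s", k, paste(format(params[[k]], trim = TRUE),
                                           collapse = ","))
            }, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a report TSV written by [write_report_tsv()]
#' @param path file path.
#' @return data frame (preamble lines skipped).
#' @export
read_report_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
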