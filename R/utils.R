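`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_columns <- function(df, required, path = "<data>") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in '%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Parse numbers that may carry thousands separators as printed in
# result tables ("4,210,682"). Returns NA for unparseable entries.
parse_number <- function(x) {
  suppressWarnings(as.numeric(gsub(",", "", trimws(as.character(x)), fixed = TRUE)))
}

# Gene symbols take part in set operations only after case folding;
# no alias mapping is attempted.
normalize_gene <- function(x) toupper(trimws(as.character(x)))

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

# Deterministic TSV writer: fixed column order, no quoting, "." decimal,
# LF endings -- same data frame always yields byte-identical files.
write_tsv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0L)
               do.call(paste, c(lapply(df, function(col) {
                 if (is.numeric(col)) format(col, trim = TRUE, scientific = FALSE, digits = 15)
                 else as.character(col)
               }), sep = "\t")))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

file_md5 <- function(path) unname(tools::md5sum(path))
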