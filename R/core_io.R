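#' Read an identified-component table
#'
#' Reads a tab-separated table of chemical components identified by
#' LC-MS (one row per compound per ion mode) and merges rows belonging
#' to the same compound across ionization modes, so that every compound
#' appears exactly once in downstream analyses.
#'
#' Expected columns: `compound_id`, `name`, `ion_mode` (`positive`/`negative`,
#' or `+`/`-`), `peak_no`, `rt_min`, `mz`, `formula`, `response`, `class`.
#' Numeric columns may carry thousands separators ("4,210,682"), which are
#' stripped on parse.
#'
#' A compound detected in both modes yields one record whose `ion_modes`
#' field lists both modes and whose response is aggregated across modes.
#' The default aggregation is the maximum, which is invariant to the order
#' in which modes are listed and never exceeds the compound's best detection;
#' `sum` and `mean` are available for sensitivity analyses.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param response_agg How to combine response values when a compound is
#'   detected in several ion modes: `"max"` (default), `"sum"` or `"mean"`.
#' @return A data frame with one row per compound: `compound_id`, `name`,
#'   `ion_modes` (comma-joined, e.g. `"negative,positive"`), `peak_positive`,
#'   `peak_negative` (NA when not detected in that mode), `rt_min`, `mz`,
#'   `formula`, `response`, `class`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("compound_id\tname\tion_mode\tpeak_no\trt_min\tmz\tformula\tresponse\tclass",
#'              "C1\tHSYA\tnegative\t11\t4.2\t611.16\tC27H32O16\t4210682\tflavonoid_glycoside",
#'              "C1\tHSYA\tpositive\t17\t4.2\t613.17\tC27H32O16\t3900000\tflavonoid_glycoside"),
#'            tf)
#' read_components(tf)
#' @export
read_components <- function(path, response_agg = c("max", "sum", "mean")) {
  response_agg <- match.arg(response_agg)
  df <- read_tsv_strict(path)
  assert_columns(df, c("compound_id", "name", "ion_mode", "rt_min", "mz",
                       "formula", "response", "class"), path)
  if (nrow(df) == 0L) {
    return(data.frame(compound_id = character(), name = character(),
                      ion_modes = character(), peak_positive = integer(),
                      peak_negative = integer(), rt_min = numeric(),
                      mz = numeric(), formula = character(),
                      response = numeric(), class = character(),
                      stringsAsFactors = FALSE))
  }
  resp <- parse_number(df$response)
  bad <- which(is.na(resp))
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s': non-numeric response at data row %d ('%s')",
                 path, bad[1L], df$response[bad[1L]]), call. = FALSE)
  }
  if (any(resp <= 0)) {
    stop(sprintf("invalid component table '%s': response values must be positive",
                 path), call. = FALSE)
  }
  mode <- canonical_ion_mode(df$ion_mode, path)
  peak <- if ("peak_no" %in% names(df)) suppressWarnings(as.integer(df$peak_no)) else NA_integer_

  agg_fun <- switch(response_agg, max = max, sum = sum, mean = mean)
  out <- lapply(split(seq_len(nrow(df)), factor(df$compound_id, levels = unique(df$compound_id))),
                function(idx) {
    modes <- sort(unique(mode[idx]))
    data.frame(
      compound_id = df$compound_id[idx[1L]],
      name = df$name[idx[1L]],
      ion_modes = paste(modes, collapse = ","),
      peak_positive = first_or_na(peak[idx][mode[idx] == "positive"]),
      peak_negative = first_or_na(peak[idx][mode[idx] == "negative"]),
      rt_min = parse_number(df$rt_min[idx[1L]]),
      mz = parse_number(df$mz[idx[1L]]),
      formula = df$formula[idx[1L]],
      response = agg_fun(resp[idx]),
      class = df$class[idx[1L]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

canonical_ion_mode <- function(x, path = "<data>") {
  x <- trimws(tolower(as.character(x)))
  x[x %in% c("+", "pos", "positive", "esi+")] <- "positive"
  x[x %in% c("-", "−", "neg", "negative", "esi-")] <- "negative"
  bad <- setdiff(unique(x), c("positive", "negative"))
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s': unknown ion mode '%s'", path, bad[1L]),
         call. = FALSE)
  }
  x
}

first_or_na <- function(x) if (length(x) == 0L || all(is.na(x))) NA_integer_ else x[!is.na(x)][1L]

#' Read compound-target predictions
#'
#' Reads a tab-separated table of predicted compound-target interactions
#' scored by chemical-fingerprint (Tanimoto) similarity. Gene symbols are
#' upper-cased; similarities must lie in \[0, 1\].
#'
#' @param path Path to a TSV with columns `compound_id`, `gene`, `tanimoto`.
#' @return A data frame with columns `compound_id`, `gene`, `tanimoto`.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_strict(path)
  assert_columns(df, c("compound_id", "gene", "tanimoto"), path)
  tanimoto <- parse_number(df$tanimoto)
  if (nrow(df) > 0L && any(is.na(tanimoto) | tanimoto < 0 | tanimoto > 1)) {
    stop(sprintf("invalid predictions '%s': tanimoto must be numeric in [0, 1]",
                 path), call. = FALSE)
  }
  data.frame(compound_id = as.character(df$compound_id),
             gene = normalize_gene(df$gene),
             tanimoto = tanimoto, stringsAsFactors = FALSE)
}

#' Read multi-source disease-gene records
#'
#' Each record associates a gene with an evidence source and the source's
#' native relevance score (e.g. a GeneCards relevance score or a DisGeNET
#' gene-disease association score). Records from score-thresholded sources
#' must carry a score.
#'
#' @param path Path to a TSV with columns `gene`, `source`, `score`.
#' @return A data frame with columns `gene`, `source` (lower-cased), `score`.
#' @export
read_disease_genes <- function(path) {
  df <- read_tsv_strict(path)
  assert_columns(df, c("gene", "source", "score"), path)
  data.frame(gene = normalize_gene(df$gene),
             source = tolower(trimws(as.character(df$source))),
             score = parse_number(df$score), stringsAsFactors = FALSE)
}

#' Read per-compound literature-evidence counts
#'
#' @param path Path to a TSV with columns `compound_id`, `n_studies`
#'   (non-negative integer counts of published studies supporting the
#'   compound's activity in the disease model).
#' @return A data frame with columns `compound_id`, `n_studies`.
#' @export
read_literature <- function(path) {
  df <- read_tsv_strict(path)
  assert_columns(df, c("compound_id", "n_studies"), path)
  n <- parse_number(df$n_studies)
  if (nrow(df) > 0L && any(is.na(n) | n < 0 | n != floor(n))) {
    stop(sprintf("invalid literature table '%s': n_studies must be non-negative integers",
                 path), call. = FALSE)
  }
  data.frame(compound_id = as.character(df$compound_id),
             n_studies = as.integer(n), stringsAsFactors = FALSE)
}

#' Read docking affinity records
#'
#' @param path Path to a TSV with columns `compound_id`, `target_gene`,
#'   `affinity_kcal_mol` (predicted binding free energy; more negative is
#'   more favorable).
#' @return A data frame with those three columns, gene symbols upper-cased.
#' @export
read_docking <- function(path) {
  df <- read_tsv_strict(path)
  assert_columns(df, c("compound_id", "target_gene", "affinity_kcal_mol"), path)
  aff <- parse_number(df$affinity_kcal_mol)
  if (nrow(df) > 0L && any(!is.finite(aff))) {
    stop(sprintf("invalid docking table '%s': affinities must be finite numbers",
                 path), call. = FALSE)
  }
  data.frame(compound_id = as.character(df$compound_id),
             target_gene = normalize_gene(df$target_gene),
             affinity_kcal_mol = aff, stringsAsFactors = FALSE)
}

#' Read gene-set annotations in GMT format
#'
#' Parses the tab-delimited GMT gene-set format (one set per line:
#' term id, description, then member genes). Member symbols are
#' upper-cased and de-duplicated per term.
#'
#' @param path Path to a GMT file.
#' @param namespace Annotation namespace for every term in the file:
#'   one of `"kegg"`, `"go_bp"`, `"go_cc"`, `"go_mf"`, `"custom"`.
#' @return An object of class `gene_set_collection`: a list of terms, each a
#'   list with `term_id`, `term_name`, `namespace`, `genes` (character vector)
#'   and `module` (initially `NA`; see [assign_modules()]).
#' @export
read_gmt <- function(path, namespace = c("custom", "kegg", "go_bp", "go_cc", "go_mf")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- vector("list", length(lines))
  seen <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("parse error in '%s' line %d: GMT lines need >= 3 tab-separated fields",
                   path, i), call. = FALSE)
    }
    genes <- unique(normalize_gene(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("parse error in '%s' line %d: term '%s' has no genes",
                   path, i, fields[1L]), call. = FALSE)
    }
    if (fields[1L] %in% seen) {
      stop(sprintf("parse error in '%s' line %d: duplicate term id '%s'",
                   path, i, fields[1L]), call. = FALSE)
    }
    seen <- c(seen, fields[1L])
    terms[[i]] <- list(term_id = fields[1L], term_name = fields[2L],
                       namespace = namespace, genes = genes, module = NA_character_)
  }
  structure(terms, class = "gene_set_collection")
}

#' Write gene-set annotations to a GMT file
#'
#' @param terms A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t) {
    paste(c(t$term_id, t$term_name, t$genes), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  ns <- table(vapply(x, `[[`, character(1), "namespace"))
  cat(sprintf("Gene set collection: %d terms (%s)\n", length(x),
              paste(sprintf("%s: %d", names(ns), as.integer(ns)), collapse = ", ")))
  invisible(x)
}
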