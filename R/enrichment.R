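#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a query of size
#' `n` drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' This is the over-representation statistic for gene-set enrichment.
#'
#' The sum is accumulated in log space (via `lchoose`) with a
#' log-sum-exp reduction, so it stays accurate deep in the tail where the
#' individual probabilities underflow.
#'
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @param n Query size.
#' @param K Annotated-set size.
#' @param N Universe size.
#' @return `P(X >= k)`, a probability in (0, 1].
#' @examples
#' hypergeometric_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (any(c(k, n, K, N) < 0) || any(c(k, n, K, N) != floor(c(k, n, K, N)))) {
    stop("k, n, K, N must be non-negative integers", call. = FALSE)
  }
  if (n > N || K > N) stop("n and K must not exceed N", call. = FALSE)
  if (k > min(n, K)) stop("k must not exceed min(n, K)", call. = FALSE)
  if (k == 0L) return(1)
  i <- k:min(n, K)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(p, 1)
}

#' DAVID-style EASE score
#'
#' A conservative variant of the hypergeometric upper tail that removes one
#' gene from the observed overlap before computing the tail: `P(X >= k - 1)`.
#' Penalizes terms supported by a single gene (an overlap of 1 scores 1).
#'
#' @inheritParams hypergeometric_upper_tail
#' @return A probability in (0, 1].
#' @export
ease_score <- function(k, n, K, N) {
  hypergeometric_upper_tail(max(k - 1L, 0L), n, K, N)
}

#' Enrichment configuration
#'
#' @param alpha Significance level on the (possibly adjusted) p-value.
#'   Default 0.05.
#' @param correction `"none"` (default; raw p-values are compared to
#'   `alpha`) or `"bh"` (Benjamini-Hochberg within each namespace).
#' @param statistic `"hypergeometric"` (default) or `"ease"`.
#' @param background `"annotation_universe"` (default: the union of all
#'   genes in the annotation collection) or an explicit character vector of
#'   background genes.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.05,
                              correction = c("none", "bh"),
                              statistic = c("hypergeometric", "ease"),
                              background = "annotation_universe") {
  correction <- match.arg(correction)
  statistic <- match.arg(statistic)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, correction = correction,
                 statistic = statistic, background = background),
            class = "enrichment_config")
}

#' Gene-set over-representation analysis
#'
#' Tests each annotated gene set for over-representation in the query set
#' using the hypergeometric upper tail (or DAVID's EASE variant). Only
#' terms with at least one query gene are reported; results are sorted by
#' ascending p-value. With `correction = "bh"` the Benjamini-Hochberg
#' adjustment is applied within each annotation namespace.
#'
#' @param query Character vector of query genes (e.g. the overlap genes or
#'   the hub targets).
#' @param annotations A `gene_set_collection` (see [read_gmt()]).
#' @param cfg An [enrichment_config()].
#' @return Data frame of class `enrichment_result` with columns `term_id`,
#'   `term_name`, `namespace`, `module`, `k` (overlap), `n` (effective query
#'   size), `K` (term size in background), `N` (background size), `p_value`,
#'   `p_adjusted`, `significant`, `genes` (comma-joined overlap genes).
#' @export
enrich <- function(query, annotations, cfg = enrichment_config()) {
  stopifnot(inherits(cfg, "enrichment_config"))
  if (length(query) == 0L) stop("query gene set is empty", call. = FALSE)
  query <- unique(normalize_gene(query))
  universe <- if (identical(cfg$background, "annotation_universe")) {
    unique(unlist(lapply(annotations, `[[`, "genes"), use.names = FALSE))
  } else {
    unique(normalize_gene(cfg$background))
  }
  query_bg <- intersect(query, universe)
  if (length(query_bg) == 0L) {
    warning("query does not intersect the background; no terms tested")
    return(empty_enrichment())
  }
  N <- length(universe)
  n <- length(query_bg)
  stat_fun <- if (cfg$statistic == "ease") ease_score else hypergeometric_upper_tail

  rows <- lapply(annotations, function(term) {
    genes_bg <- intersect(term$genes, universe)
    hit <- intersect(query_bg, genes_bg)
    k <- length(hit)
    if (k == 0L) return(NULL)
    data.frame(term_id = term$term_id, term_name = term$term_name,
               namespace = term$namespace,
               module = term$module %||% NA_character_,
               k = k, n = n, K = length(genes_bg), N = N,
               p_value = stat_fun(k, n, length(genes_bg), N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty_enrichment())
  if (cfg$correction == "bh") {
    rows$p_adjusted <- NA_real_
    for (ns in unique(rows$namespace)) {
      idx <- rows$namespace == ns
      rows$p_adjusted[idx] <- stats::p.adjust(rows$p_value[idx], method = "BH")
    }
  } else {
    rows$p_adjusted <- rows$p_value
  }
  rows$significant <- rows$p_adjusted < cfg$alpha
  # overlap genes, comma-joined for tabular output
  rows$genes <- vapply(seq_len(nrow(rows)), function(i) {
    term <- Find(function(t) t$term_id == rows$term_id[i] &&
                   t$namespace == rows$namespace[i], annotations)
    paste(sort(intersect(unique(normalize_gene(query)), term$genes)), collapse = ",")
  }, character(1))
  rows <- rows[order(rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_result", "data.frame")
  rows
}

empty_enrichment <- function() {
  out <- data.frame(term_id = character(), term_name = character(),
                    namespace = character(), module = character(),
                    k = integer(), n = integer(), K = integer(), N = integer(),
                    p_value = numeric(), p_adjusted = numeric(),
                    significant = logical(), genes = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Label enrichment results with functional modules
#'
#' Pathway terms are grouped into broad functional modules (e.g.
#' inflammation, metabolism) supplied as an explicit curated mapping;
#' terms missing from the mapping are labeled `"other"`. The mapping must
#' not assign two conflicting labels to the same term.
#'
#' @param results An `enrichment_result` (or any data frame with a
#'   `term_id` column), or a `gene_set_collection`.
#' @param module_map Named character vector or list: term id -> module
#'   label. May be partial or empty.
#' @return The input with its `module` column (or per-term `module` field)
#'   filled in.
#' @export
assign_modules <- function(results, module_map = character()) {
  module_map <- unlist(module_map)
  if (length(module_map) > 0L) {
    dup <- names(module_map)[duplicated(names(module_map))]
    conflicting <- unique(dup[vapply(dup, function(id) {
      length(unique(module_map[names(module_map) == id])) > 1L
    }, logical(1))])
    if (length(conflicting) > 0L) {
      stop(sprintf("conflicting module labels for term(s): %s",
                   paste(conflicting, collapse = ", ")), call. = FALSE)
    }
    module_map <- module_map[!duplicated(names(module_map))]
  }
  lookup <- function(id) {
    if (id %in% names(module_map)) unname(module_map[[id]]) else "other"
  }
  if (inherits(results, "gene_set_collection")) {
    out <- lapply(results, function(t) { t$module <- lookup(t$term_id); t })
    class(out) <- "gene_set_collection"
    return(out)
  }
  results$module <- vapply(results$term_id, lookup, character(1), USE.NAMES = FALSE)
  results
}
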