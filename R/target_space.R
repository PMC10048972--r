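#' Target-space configuration
#'
#' Thresholds for building the drug-target and disease-gene sets.
#' The similarity cutoff on compound-target predictions is inclusive
#' (a Tanimoto score equal to the cutoff passes); disease-source score
#' cutoffs are strict by default (a GeneCards score of exactly 10 is
#' dropped). Sources configured with a `NULL` threshold (the curated
#' `tcmip` extract by default) always pass.
#'
#' @param tanimoto_min Minimum Tanimoto similarity for a compound-target
#'   prediction to be retained (inclusive). Default 0.7.
#' @param source_thresholds Named list mapping each disease-gene source to
#'   either `NULL` (no threshold) or `list(comparator, cutoff)` with
#'   comparator `">"` or `">="`.
#' @return An object of class `target_space_config`.
#' @export
target_space_config <- function(tanimoto_min = 0.7,
                                source_thresholds = list(
                                  genecards = list(">", 10),
                                  disgenet = list(">", 0.1),
                                  tcmip = NULL)) {
  if (!is.numeric(tanimoto_min) || length(tanimoto_min) != 1L ||
      is.na(tanimoto_min) || tanimoto_min < 0 || tanimoto_min > 1) {
    stop("tanimoto_min must be a single number in [0, 1]", call. = FALSE)
  }
  for (src in names(source_thresholds)) {
    thr <- source_thresholds[[src]]
    if (is.null(thr)) next
    if (length(thr) != 2L || !thr[[1]] %in% c(">", ">=") || !is.finite(thr[[2]])) {
      stop(sprintf("threshold for source '%s' must be list(\">\" or \">=\", finite cutoff)", src),
           call. = FALSE)
    }
  }
  structure(list(tanimoto_min = tanimoto_min,
                 source_thresholds = source_thresholds),
            class = "target_space_config")
}

#' Filter compound-target predictions by similarity
#'
#' Retains predictions with Tanimoto similarity at or above the configured
#' cutoff and collects the surviving target genes per compound,
#' de-duplicated.
#'
#' @param preds Data frame of predictions (see [read_predictions()]).
#' @param cfg A [target_space_config()].
#' @return Named list: compound id -> character vector of retained genes.
#'   Compounds with no retained prediction are absent from the result.
#' @export
filter_predictions <- function(preds, cfg = target_space_config()) {
  stopifnot(inherits(cfg, "target_space_config"))
  if (nrow(preds) == 0L) return(stats::setNames(list(), character()))
  keep <- preds$tanimoto >= cfg$tanimoto_min
  preds <- preds[keep, , drop = FALSE]
  if (nrow(preds) == 0L) return(stats::setNames(list(), character()))
  lapply(split(normalize_gene(preds$gene), preds$compound_id), unique)
}

#' Collect the disease-gene set under per-source thresholds
#'
#' Applies each source's score threshold record by record and returns the
#' union of passing genes across sources. A gene therefore enters the
#' disease set as soon as any one source supports it strongly enough.
#'
#' @param records Data frame of disease-gene records
#'   (see [read_disease_genes()]).
#' @param cfg A [target_space_config()].
#' @return Sorted character vector of disease genes.
#' @export
collect_disease_genes <- function(records, cfg = target_space_config()) {
  stopifnot(inherits(cfg, "target_space_config"))
  if (nrow(records) == 0L) return(character())
  unknown <- setdiff(unique(records$source), names(cfg$source_thresholds))
  if (length(unknown) > 0L) {
    stop(sprintf("no threshold configured for disease-gene source(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pass <- vapply(seq_len(nrow(records)), function(i) {
    thr <- cfg$source_thresholds[[records$source[i]]]
    if (is.null(thr)) return(TRUE)
    s <- records$score[i]
    if (is.na(s)) {
      stop(sprintf("record %d (gene %s, source %s) lacks the score its source requires",
                   i, records$gene[i], records$source[i]), call. = FALSE)
    }
    if (thr[[1]] == ">") s > thr[[2]] else s >= thr[[2]]
  }, logical(1))
  sort(unique(normalize_gene(records$gene[pass])))
}

#' Intersect drug targets with disease genes
#'
#' The overlap between the compound-predicted target space and the
#' disease-gene space defines the candidate genes through which the herb
#' can plausibly act on the disease (the sets a Venn diagram would show).
#'
#' @param drug_targets Either the per-compound list from
#'   [filter_predictions()] or a plain character vector of genes.
#' @param disease_genes Character vector from [collect_disease_genes()].
#' @return An object of class `overlap_result`: list with `drug_targets`,
#'   `disease_genes`, `overlap` (sorted character vectors),
#'   `per_compound_targets` (the input list when one was given) and `sizes`.
#' @export
intersect_targets <- function(drug_targets, disease_genes) {
  per_compound <- NULL
  if (is.list(drug_targets)) {
    per_compound <- lapply(drug_targets, function(g) unique(normalize_gene(g)))
    drug_set <- sort(unique(unlist(per_compound, use.names = FALSE)))
  } else {
    drug_set <- sort(unique(normalize_gene(drug_targets)))
  }
  disease_set <- sort(unique(normalize_gene(disease_genes)))
  overlap <- intersect(drug_set, disease_set)
  structure(list(drug_targets = drug_set,
                 disease_genes = disease_set,
                 overlap = overlap,
                 per_compound_targets = per_compound,
                 sizes = c(drug_targets = length(drug_set),
                           disease_genes = length(disease_set),
                           overlap = length(overlap))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Target-space overlap: %d drug targets, %d disease genes, %d in common\n",
              x$sizes[["drug_targets"]], x$sizes[["disease_genes"]],
              x$sizes[["overlap"]]))
  invisible(x)
}
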