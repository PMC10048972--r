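#' Screening criteria for hub targets and key components
#'
#' Comparators for the median-threshold screens. Degree comparisons are
#' strict by default (a node at the median is not a hub), while the
#' literature and response criteria are inclusive: a compound whose study
#' count or MS response sits exactly on the median still passes. A
#' component is selected when at least `min_criteria_met` of the three
#' criteria -- network topology, literature mining, quantitative MS
#' response -- fire.
#'
#' @param hub_rule Comparator for target degree vs the target-degree
#'   median: `">"` (default) or `">="`.
#' @param component_degree_rule Comparator for component degree vs the
#'   component-degree median: `">"` (default) or `">="`.
#' @param literature_rule Comparator for study counts vs the literature
#'   median: `">="` (default) or `">"`.
#' @param response_rule Comparator for MS response vs the response median:
#'   `">="` (default) or `">"`.
#' @param min_criteria_met How many of the three component criteria must
#'   fire for selection (1-3; default 2).
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(hub_rule = ">",
                               component_degree_rule = ">",
                               literature_rule = ">=",
                               response_rule = ">=",
                               min_criteria_met = 2L) {
  cmp_ok <- function(x) is.character(x) && length(x) == 1L && x %in% c(">", ">=")
  stopifnot(cmp_ok(hub_rule), cmp_ok(component_degree_rule),
            cmp_ok(literature_rule), cmp_ok(response_rule))
  min_criteria_met <- as.integer(min_criteria_met)
  if (is.na(min_criteria_met) || min_criteria_met < 1L || min_criteria_met > 3L) {
    stop("min_criteria_met must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(hub_rule = hub_rule,
                 component_degree_rule = component_degree_rule,
                 literature_rule = literature_rule,
                 response_rule = response_rule,
                 min_criteria_met = min_criteria_met),
            class = "screening_criteria")
}

compare_by <- function(x, cutoff, rule) {
  if (rule == ">") x > cutoff else x >= cutoff
}

#' Median thresholds
#'
#' Container for the four medians driving the screens. Normally produced by
#' [compute_medians()] from the data themselves; constructing one directly
#' is useful when replaying published thresholds.
#'
#' @param target_degree_median Median degree over target-partition nodes.
#' @param component_degree_median Median degree over component-partition
#'   nodes.
#' @param response_median Median MS response over all ingested components.
#' @param literature_median Median study count (over the topology-passing
#'   candidate compounds; see [compute_medians()]).
#' @return An object of class `median_thresholds`.
#' @export
median_thresholds <- function(target_degree_median = NA_real_,
                              component_degree_median = NA_real_,
                              response_median = NA_real_,
                              literature_median = NA_real_) {
  structure(list(target_degree_median = as.numeric(target_degree_median),
                 component_degree_median = as.numeric(component_degree_median),
                 response_median = as.numeric(response_median),
                 literature_median = as.numeric(literature_median)),
            class = "median_thresholds")
}

#' Compute the median thresholds from the data
#'
#' All four thresholds are re-computed from their populations, never
#' hard-coded: the target-degree median over target-partition nodes of the
#' network; the component-degree median over component-partition nodes; the
#' response median over every ingested component (not only those in the
#' network); and the literature median over the compounds that pass the
#' component-degree (topology) criterion -- literature mining is a check on
#' the topologically nominated candidates, so its median is taken within
#' that candidate pool. Compounds without a literature record count as 0
#' studies.
#'
#' @param metrics Node metrics from [node_metrics()] (must include the
#'   `partition` column).
#' @param literature Data frame `compound_id`, `n_studies`
#'   (see [read_literature()]); may be `NULL`.
#' @param components Component table (see [read_components()]); its
#'   `response` column defines the response population.
#' @param criteria A [screening_criteria()] (the component-degree rule
#'   determines the literature candidate pool).
#' @return A [median_thresholds()].
#' @export
compute_medians <- function(metrics, literature, components,
                            criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  tdeg <- metrics$degree[metrics$partition == "target"]
  cdeg <- metrics$degree[metrics$partition == "component"]
  if (length(tdeg) == 0L) stop("empty population: no target nodes in metrics", call. = FALSE)
  if (length(cdeg) == 0L) stop("empty population: no component nodes in metrics", call. = FALSE)
  if (is.null(components) || nrow(components) == 0L) {
    stop("empty population: no components for the response median", call. = FALSE)
  }
  target_degree_median <- stats::median(tdeg)
  component_degree_median <- stats::median(cdeg)
  response_median <- stats::median(components$response)

  candidates <- metrics$node_id[metrics$partition == "component" &
                                  compare_by(metrics$degree,
                                             component_degree_median,
                                             criteria$component_degree_rule)]
  lit <- literature_counts_for(candidates, literature)
  if (length(lit) == 0L) {
    # no topology-passing candidates: fall back to the full compound pool
    lit <- literature_counts_for(metrics$node_id[metrics$partition == "component"],
                                 literature)
  }
  median_thresholds(target_degree_median, component_degree_median,
                    response_median, stats::median(lit))
}

literature_counts_for <- function(ids, literature) {
  if (length(ids) == 0L) return(numeric())
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  if (!is.null(literature) && nrow(literature) > 0L) {
    hit <- literature$compound_id %in% ids
    counts[literature$compound_id[hit]] <- literature$n_studies[hit]
  }
  counts
}

#' Screen hub targets by the median-degree rule
#'
#' Target nodes whose whole-network degree exceeds the target-degree median
#' (strictly, by default) are nominated as hub targets. Results are ranked
#' by degree, ties broken alphabetically.
#'
#' @param metrics Node metrics from [node_metrics()].
#' @param thresholds A [median_thresholds()] (only `target_degree_median`
#'   is used); defaults to computing the median from `metrics` itself.
#' @param criteria A [screening_criteria()].
#' @return Data frame of selected targets: `gene`, `degree`, `closeness`,
#'   `betweenness`, sorted by decreasing degree then gene symbol.
#' @export
screen_hub_targets <- function(metrics, thresholds = NULL,
                               criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  tgt <- unique(metrics[metrics$partition == "target",
                        intersect(c("node_id", "degree", "closeness", "betweenness"),
                                  names(metrics)), drop = FALSE])
  med <- if (is.null(thresholds) || is.na(thresholds$target_degree_median)) {
    stats::median(tgt$degree)
  } else {
    thresholds$target_degree_median
  }
  sel <- tgt[compare_by(tgt$degree, med, criteria$hub_rule), , drop = FALSE]
  sel <- sel[order(-sel$degree, sel$node_id), , drop = FALSE]
  out <- data.frame(gene = sel$node_id, degree = sel$degree,
                    closeness = if ("closeness" %in% names(sel)) sel$closeness else NA_real_,
                    betweenness = if ("betweenness" %in% names(sel)) sel$betweenness else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "target_degree_median") <- med
  out
}

#' Screen key components by the two-of-three evidence rule
#'
#' Each candidate compound is evaluated against three criteria:
#' \describe{
#'   \item{topology}{network degree above the component-degree median
#'     (strict by default);}
#'   \item{literature}{number of supporting published studies at or above
#'     the literature median (compounds without a record count as 0);}
#'   \item{quantitation}{MS response value at or above the response median
#'     (a proxy for abundance in the extract).}
#' }
#' Compounds meeting at least `min_criteria_met` (default 2) of the three
#' are selected. The returned audit trail records which criteria fired for
#' every candidate.
#'
#' @param metrics Node metrics from [node_metrics()] (component-partition
#'   rows define the candidates and their degrees).
#' @param thresholds A [median_thresholds()] with all four medians set
#'   (see [compute_medians()]).
#' @param components Component table supplying `response` per compound.
#' @param literature Data frame `compound_id`, `n_studies`; may be `NULL`.
#' @param criteria A [screening_criteria()].
#' @return Data frame of class `component_screen`: one row per candidate
#'   with `compound_id`, `degree`, `n_studies`, `response`,
#'   `passes_topology`, `passes_literature`, `passes_quantitation`,
#'   `criteria_passed` (comma-joined names), `n_criteria`, `selected`;
#'   sorted with selected compounds first, then by decreasing degree.
#' @export
screen_key_components <- function(metrics, thresholds, components,
                                  literature = NULL,
                                  criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"),
            inherits(thresholds, "median_thresholds"))
  comp <- unique(metrics[metrics$partition == "component",
                         c("node_id", "degree"), drop = FALSE])
  resp <- stats::setNames(components$response, components$compound_id)
  lit <- literature_counts_for(comp$node_id, literature)
  missing_resp <- setdiff(comp$node_id, names(resp))
  if (length(missing_resp) > 0L) {
    stop(sprintf("no response value for network compound(s): %s",
                 paste(utils::head(missing_resp, 3L), collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(
    compound_id = comp$node_id,
    degree = comp$degree,
    n_studies = as.integer(lit[comp$node_id]),
    response = as.numeric(resp[comp$node_id]),
    stringsAsFactors = FALSE)
  out$passes_topology <- compare_by(out$degree, thresholds$component_degree_median,
                                    criteria$component_degree_rule)
  out$passes_literature <- compare_by(out$n_studies, thresholds$literature_median,
                                      criteria$literature_rule)
  out$passes_quantitation <- compare_by(out$response, thresholds$response_median,
                                        criteria$response_rule)
  fired <- cbind(topology = out$passes_topology,
                 literature = out$passes_literature,
                 quantitation = out$passes_quantitation)
  out$criteria_passed <- apply(fired, 1L, function(f)
    paste(colnames(fired)[f], collapse = ","))
  out$n_criteria <- as.integer(rowSums(fired))
  out$selected <- out$n_criteria >= criteria$min_criteria_met
  out <- out[order(-out$selected, -out$degree, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("component_screen", "data.frame")
  attr(out, "thresholds") <- thresholds
  attr(out, "criteria") <- criteria
  out
}

#' Docking-affinity threshold screen
#'
#' A compound-target pose passes when its predicted binding free energy is
#' strictly below (more negative than) the cutoff; an affinity exactly at
#' the cutoff fails.
#'
#' @param records Docking records (see [read_docking()]).
#' @param cutoff Affinity cutoff in kcal/mol. Default -5.0.
#' @return The records with a logical `pass` column, plus a
#'   `"per_target_pass"` attribute tabulating passing compounds per target.
#' @export
screen_docking <- function(records, cutoff = -5.0) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  out <- records
  out$pass <- records$affinity_kcal_mol < cutoff
  per_target <- if (nrow(out) > 0L) {
    tab <- tapply(out$pass, out$target_gene, sum)
    data.frame(target_gene = names(tab), n_pass = as.integer(tab),
               n_records = as.integer(table(out$target_gene)[names(tab)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(target_gene = character(), n_pass = integer(),
               n_records = integer(), stringsAsFactors = FALSE)
  }
  attr(out, "per_target_pass") <- per_target
  out
}

#' @export
print.component_screen <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("Key-component screen: %d candidates, %d selected (>= %d of 3 criteria)\n",
              nrow(x), sum(x$selected), attr(x, "criteria")$min_criteria_met))
  cat(sprintf("  medians: component degree %.6g, literature %.6g, response %.6g\n",
              thr$component_degree_median, thr$literature_median,
              thr$response_median))
  print.data.frame(utils::head(as.data.frame(x), 15L))
  invisible(x)
}
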