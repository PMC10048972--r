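#' Path to a packaged example file
#'
#' The package ships small plain-text fixtures: transcriptions of the two
#' published result tables of the motivating safflower / myocardial
#' ischemia-reperfusion study (`published_hub_targets.tsv`, the 31 hub
#' targets with their centralities; `published_key_components.tsv`, the 11
#' key components with their target lists, MS responses and study counts),
#' and synthetic stand-ins for inputs whose originals are not publicly
#' deposited (`synthetic_components_79.tsv`, an identified-component table
#' with the published compound count and ion-mode split;
#' `synthetic_pathways_34.gmt` with `synthetic_pathway_modules.tsv`, a
#' 34-pathway annotation set with functional-module labels). Files with a
#' `synthetic_` prefix have generated content and are not transcriptions.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
phytonet_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "phytonet")))
  }
  path <- system.file("extdata", file, package = "phytonet")
  if (!nzchar(path)) stop(sprintf("no packaged file '%s'", file), call. = FALSE)
  path
}

#' Published hub-target table
#'
#' The 31 hub targets of the motivating study with their degree, closeness
#' and betweenness in the full compound-target-pathway network, as printed.
#' Useful as a desk-scale replay of the hub screen: with the published
#' target-degree median of 6, every listed target passes the strict
#' degree-above-median rule.
#'
#' @return Data frame: `gene`, `degree`, `closeness`, `betweenness`.
#' @export
published_hub_targets <- function() {
  read_tsv_strict(phytonet_example("published_hub_targets.tsv"))
}

#' Published key-component table
#'
#' The 11 key components of the motivating study: ion-mode peak
#' annotations, their targets among the network's effective target set,
#' the printed network degree, the MS response value and the
#' literature-study count.
#'
#' @return Data frame: `compound_id`, `ion_peaks`, `targets` (comma-joined),
#'   `degree_published`, `response`, `n_studies`.
#' @export
published_key_components <- function() {
  df <- read_tsv_strict(phytonet_example("published_key_components.tsv"))
  df$response <- parse_number(df$response)
  df$degree_published <- as.integer(df$degree_published)
  df$n_studies <- as.integer(df$n_studies)
  df
}

#' Compound-target network reconstructed from the published component table
#'
#' Rebuilds the component-target layer from the per-component target lists
#' of [published_key_components()] (the pathway layer is not printed and is
#' omitted). Component degrees recomputed on this network can be checked
#' against the published degree column.
#'
#' @return A `tripartite_network` with 11 component nodes.
#' @export
published_component_network <- function() {
  df <- published_key_components()
  per_compound <- stats::setNames(
    lapply(strsplit(df$targets, ",", fixed = TRUE), trimws),
    df$compound_id)
  build_network(per_compound)
}
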