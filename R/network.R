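#' Construct a tripartite compound-target-pathway network
#'
#' Low-level constructor and validator. Edges may only connect a component
#' (compound) node to a target node, or a target node to a pathway node;
#' self loops and within-partition edges are rejected, and node ids must be
#' unique across the three partitions.
#'
#' @param nodes Data frame with columns `node_id`, `partition`
#'   (`"component"`, `"target"` or `"pathway"`).
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `evidence` (free-text provenance, e.g. `"prediction"` or `"membership"`).
#' @return An object of class `tripartite_network`.
#' @seealso [build_network()] for the high-level assembly from evidence.
#' @export
tripartite_network <- function(nodes, edges) {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      partition = as.character(nodes$partition),
                      stringsAsFactors = FALSE)
  if (is.null(edges$evidence)) edges$evidence <- NA_character_
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      evidence = as.character(edges$evidence),
                      stringsAsFactors = FALSE)
  bad_part <- setdiff(unique(nodes$partition), c("component", "target", "pathway"))
  if (length(bad_part) > 0L) {
    stop(sprintf("unknown partition label(s): %s", paste(bad_part, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("node ids must be unique across partitions", call. = FALSE)
  }
  part <- stats::setNames(nodes$partition, nodes$node_id)
  unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(unknown) > 0L) {
    stop(sprintf("edge endpoint(s) not in node table: %s",
                 paste(utils::head(unknown, 3L), collapse = ", ")), call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self loops are not allowed", call. = FALSE)
  pair <- paste(pmin(part[edges$from], part[edges$to]),
                pmax(part[edges$from], part[edges$to]))
  ok <- pair %in% c("component target", "pathway target")
  if (!all(ok)) {
    stop("edges must connect component-target or target-pathway partitions",
         call. = FALSE)
  }
  # canonical undirected representation: lexicographically ordered endpoints,
  # duplicates dropped
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[keep], to = b[keep],
                      evidence = edges$evidence[keep], stringsAsFactors = FALSE)
  o <- order(edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  nodes <- nodes[order(nodes$partition, nodes$node_id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' Assemble the tripartite network from screened evidence
#'
#' Builds the compound-target-pathway graph used for topological screening.
#' A compound is linked to a target when the target survived the similarity
#' filter for that compound *and* belongs to the effective target set
#' (typically the targets found in the disease-relevant pathways); a target
#' is linked to a pathway when it is a member of that pathway's gene set.
#' Nodes left without any edge are dropped.
#'
#' @param per_compound_targets Named list mapping compound id to a character
#'   vector of predicted target genes (e.g. from [filter_predictions()]).
#' @param selected_terms A `gene_set_collection` of the pathway terms to
#'   include (may be empty, giving a bipartite compound-target graph).
#' @param effective_targets Character vector of target genes eligible for
#'   inclusion; defaults to every predicted target.
#' @return A `tripartite_network`.
#' @examples
#' net <- build_network(list(cmpA = c("TP53")),
#'                      selected_terms = structure(list(
#'                        list(term_id = "path1", term_name = "p",
#'                             namespace = "kegg", genes = "TP53",
#'                             module = NA_character_)),
#'                        class = "gene_set_collection"))
#' nrow(net$edges)  # 2: cmpA-TP53 and TP53-path1
#' @export
build_network <- function(per_compound_targets, selected_terms = NULL,
                          effective_targets = NULL) {
  if (is.null(selected_terms)) selected_terms <- structure(list(), class = "gene_set_collection")
  all_pred <- unique(normalize_gene(unlist(per_compound_targets, use.names = FALSE)))
  if (is.null(effective_targets)) effective_targets <- all_pred
  effective_targets <- unique(normalize_gene(effective_targets))

  ct <- do.call(rbind, lapply(names(per_compound_targets), function(cid) {
    genes <- intersect(unique(normalize_gene(per_compound_targets[[cid]])),
                       effective_targets)
    if (length(genes) == 0L) return(NULL)
    data.frame(from = cid, to = genes, evidence = "prediction",
               stringsAsFactors = FALSE)
  }))
  targets_in_net <- unique(ct$to)
  tp <- do.call(rbind, lapply(selected_terms, function(term) {
    genes <- intersect(term$genes, targets_in_net)
    if (length(genes) == 0L) return(NULL)
    data.frame(from = genes, to = term$term_id, evidence = "membership",
               stringsAsFactors = FALSE)
  }))
  edges <- rbind(ct, tp)
  if (is.null(edges) || nrow(edges) == 0L) {
    stop("degenerate network: no edges survive the filters", call. = FALSE)
  }
  comp_ids <- unique(ct$from)
  path_ids <- if (is.null(tp)) character() else unique(tp$to)
  nodes <- data.frame(
    node_id = c(comp_ids, targets_in_net, path_ids),
    partition = c(rep("component", length(comp_ids)),
                  rep("target", length(targets_in_net)),
                  rep("pathway", length(path_ids))),
    stringsAsFactors = FALSE)
  tripartite_network(nodes, edges)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$node_id)
  igraph::set_vertex_attr(g, "partition", value = net$nodes$partition)
}

#' Node degree
#'
#' Number of edges incident to each node of the tripartite network.
#'
#' @param net A `tripartite_network`.
#' @return Named integer vector over all nodes.
#' @export
centrality_degree <- function(net) {
  d <- integer(nrow(net$nodes))
  names(d) <- net$nodes$node_id
  tab <- table(c(net$edges$from, net$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Closeness centrality
#'
#' Within-component closeness: for a node `v` in a connected component of
#' size `m`, closeness is `(m - 1) / sum of unweighted shortest-path
#' distances from v to the other members of its component`. This is the
#' convention used by Cytoscape's Network Analyzer, keeps values in
#' \[0, 1\], and treats cross-component distances as undefined rather than
#' infinite. Isolated nodes get 0.
#'
#' @param net A `tripartite_network`.
#' @return Named numeric vector over all nodes.
#' @export
centrality_closeness <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g)
  cl <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else length(di) / sum(di)
  }, numeric(1))
  stats::setNames(cl, rownames(d))
}

#' Betweenness centrality
#'
#' Shortest-path betweenness over unordered node pairs excluding the
#' endpoints, normalized by `2 / ((n - 1) (n - 2))` where `n` is the total
#' number of network nodes, so values lie in \[0, 1\] (Cytoscape Network
#' Analyzer convention). For networks with fewer than 3 nodes all values
#' are 0.
#'
#' @param net A `tripartite_network`.
#' @return Named numeric vector over all nodes.
#' @export
centrality_betweenness <- function(net) {
  n <- nrow(net$nodes)
  if (n < 3L) {
    return(stats::setNames(numeric(n), net$nodes$node_id))
  }
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b * 2 / ((n - 1) * (n - 2))
}

#' Topological metrics for every node
#'
#' Computes the three topological parameters used for hub screening --
#' degree, closeness and betweenness -- on the whole tripartite graph.
#'
#' @param net A `tripartite_network`.
#' @return Data frame with columns `node_id`, `partition`, `degree`,
#'   `closeness`, `betweenness`, one row per node.
#' @export
node_metrics <- function(net) {
  deg <- centrality_degree(net)
  clo <- centrality_closeness(net)
  btw <- centrality_betweenness(net)
  out <- data.frame(node_id = net$nodes$node_id,
                    partition = net$nodes$partition,
                    degree = as.integer(deg[net$nodes$node_id]),
                    closeness = as.numeric(clo[net$nodes$node_id]),
                    betweenness = as.numeric(btw[net$nodes$node_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.tripartite_network <- function(x, ...) {
  np <- table(factor(x$nodes$partition, levels = c("component", "target", "pathway")))
  cat(sprintf("Tripartite network: %d nodes (%d components, %d targets, %d pathways), %d edges\n",
              nrow(x$nodes), np[["component"]], np[["target"]], np[["pathway"]],
              nrow(x$edges)))
  invisible(x)
}

#' Export a tripartite network
#'
#' Writes the network in one of three interchange formats. GraphML carries
#' the node partition labels as a node attribute; SIF (simple interaction
#' format) encodes one edge per line as `source <relation> target`; the
#' edge TSV pairs an `edges` file with a sibling `<path>.nodes.tsv` holding
#' the partition labels. Reading back a written network reproduces the node
#' set, edge set and partition labels exactly.
#'
#' @param net A `tripartite_network`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"edge_tsv"`.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    g <- igraph::set_edge_attr(g, "evidence",
                               value = ifelse(is.na(net$edges$evidence), "",
                                              net$edges$evidence))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    rel <- ifelse(is.na(net$edges$evidence), "pp", net$edges$evidence)
    lines <- paste(net$edges$from, rel, net$edges$to, sep = "\t")
    # nodes absent from every edge still need a line of their own
    iso <- setdiff(net$nodes$node_id, c(net$edges$from, net$edges$to))
    con <- file(path, open = "wb"); on.exit(close(con))
    writeLines(c(lines, iso), con = con, sep = "\n", useBytes = TRUE)
  } else {
    write_tsv_stable(net$edges, path)
    write_tsv_stable(net$nodes, paste0(path, ".nodes.tsv"))
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to a `.graphml` or edge-TSV export. SIF carries no
#'   partition labels and cannot be read back into a `tripartite_network`.
#' @param format `"graphml"` or `"edge_tsv"`; inferred from the file
#'   extension when missing.
#' @return A `tripartite_network`.
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edge_tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(node_id = igraph::V(g)$name,
                        partition = igraph::V(g)$partition,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ev <- igraph::edge_attr(g, "evidence") %||% rep(NA_character_, nrow(el))
    edges <- data.frame(from = el[, 1], to = el[, 2], evidence = ev,
                        stringsAsFactors = FALSE)
  } else if (format == "edge_tsv") {
    edges <- read_tsv_strict(path)
    nodes <- read_tsv_strict(paste0(path, ".nodes.tsv"))
  } else {
    stop(sprintf("unsupported network format '%s'", format), call. = FALSE)
  }
  edges$evidence[!is.na(edges$evidence) & edges$evidence == ""] <- NA_character_
  tripartite_network(nodes, edges)
}
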