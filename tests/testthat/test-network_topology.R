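test_that("one compound hitting one target in one pathway gives 3 nodes and 2 edges", {
  net <- build_network(list(cmpA = "TP53"),
                       structure(list(list(term_id = "p1", term_name = "p",
                                           namespace = "kegg", genes = c("TP53", "EGFR"),
                                           module = NA_character_)),
                                 class = "gene_set_collection"))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_error(build_network(list(cmpA = "TP53"), effective_targets = "OTHER"),
               "degenerate")
})

test_that("component degrees recomputed from the published edges match the printed rows", {
  net <- published_component_network()
  deg <- centrality_degree(net)
  expect_equal(unname(deg[["HSYA"]]), 2L)          # PTGS1 + HK1
  expect_equal(unname(deg[["quercetin"]]), 12L)
  m <- node_metrics(net)
  expect_equal(m$degree[m$node_id == "HSYA"], 2L)
})

test_that("edge counts equal retained-target plus membership pair counts", {
  set.seed(91)
  for (rep in 1:20) {
    per <- lapply(stats::setNames(1:5, sprintf("c%d", 1:5)), function(i)
      sample(sprintf("T%02d", 1:12), sample(1:6, 1)))
    terms <- structure(lapply(1:3, function(j)
      list(term_id = sprintf("p%d", j), term_name = "x", namespace = "custom",
           genes = sample(sprintf("T%02d", 1:12), 5), module = NA_character_)),
      class = "gene_set_collection")
    net <- build_network(per, terms)
    expected_ct <- sum(lengths(lapply(per, unique)))
    used <- unique(unlist(per))
    expected_tp <- sum(vapply(terms, function(t)
      length(intersect(t$genes, used)), integer(1)))
    expect_equal(nrow(net$edges), expected_ct + expected_tp)
    # handshake lemma
    expect_equal(sum(centrality_degree(net)), 2L * nrow(net$edges))
  }
})

test_that("the tripartite constraint rejects malformed graphs", {
  nodes <- data.frame(node_id = c("a", "b", "T1"),
                      partition = c("component", "component", "target"))
  expect_error(tripartite_network(nodes, data.frame(from = "a", to = "b")),
               "partition")
  expect_error(tripartite_network(nodes, data.frame(from = "a", to = "a")),
               "self loop")
  expect_error(tripartite_network(
    data.frame(node_id = c("a", "a"), partition = c("component", "target")),
    data.frame(from = "a", to = "a")), "unique")
  expect_error(tripartite_network(nodes, data.frame(from = "a", to = "Z")),
               "node table")
})

path_net <- function() {
  tripartite_network(
    data.frame(node_id = c("a", "b", "c"),
               partition = c("component", "target", "pathway")),
    data.frame(from = c("a", "b"), to = c("b", "c")))
}

test_that("closeness and betweenness match hand-computed path-graph values", {
  net <- path_net()
  clo <- centrality_closeness(net)
  expect_equal(unname(clo[["b"]]), 1.0)
  expect_equal(unname(clo[["a"]]), 2 / 3)
  btw <- centrality_betweenness(net)
  expect_equal(unname(btw[["b"]]), 1.0)  # lone middle pair, normalization 2/(2*1)
  expect_equal(unname(btw[["a"]]), 0)
})

test_that("a two-node network has zero betweenness and unit closeness", {
  net <- tripartite_network(
    data.frame(node_id = c("a", "T"), partition = c("component", "target")),
    data.frame(from = "a", to = "T"))
  expect_equal(unname(centrality_betweenness(net)), c(0, 0))
  expect_equal(unname(centrality_closeness(net)), c(1, 1))
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(77)
  for (rep in 1:60) {
    net <- random_tripartite(n_comp = sample(2:3, 1), n_tgt = sample(2:5, 1),
                             n_path = sample(2:4, 1), p = runif(1, 0.25, 0.7))
    nodes <- net$nodes$node_id
    expect_equal(centrality_closeness(net)[nodes],
                 oracle_closeness(nodes, net$edges)[nodes], tolerance = 1e-12)
    expect_equal(centrality_betweenness(net)[nodes],
                 oracle_betweenness(nodes, net$edges)[nodes], tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(13)
  net <- random_tripartite(n_comp = 3, n_tgt = 5, n_path = 4, p = 0.4)
  relabel <- stats::setNames(sprintf("node%02d", sample(nrow(net$nodes))),
                             net$nodes$node_id)
  net2 <- tripartite_network(
    data.frame(node_id = unname(relabel[net$nodes$node_id]),
               partition = net$nodes$partition),
    data.frame(from = unname(relabel[net$edges$from]),
               to = unname(relabel[net$edges$to])))
  for (fn in list(centrality_degree, centrality_closeness, centrality_betweenness)) {
    a <- fn(net); b <- fn(net2)
    expect_equal(unname(b[unname(relabel[names(a)])]), unname(a), tolerance = 1e-12)
  }
})

test_that("metrics are computed per component with cross-component distances undefined", {
  # two disjoint compound-target pairs: closeness stays 1 within each pair
  net <- tripartite_network(
    data.frame(node_id = c("a", "T1", "b", "T2"),
               partition = c("component", "target", "component", "target")),
    data.frame(from = c("a", "b"), to = c("T1", "T2")))
  expect_equal(unname(centrality_closeness(net)), rep(1, 4))
  expect_equal(unname(centrality_betweenness(net)), rep(0, 4))
})
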