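test_that("components detected in both ion modes merge into one record", {
  path <- write_lines_tsv(c(
    components_header,
    "C1\tHSYA\tnegative\t11\t4.2\t611.16\tC27H32O16\t100\tflavonoid_glycoside",
    "C1\tHSYA\tpositive\t17\t4.2\t613.17\tC27H32O16\t250\tflavonoid_glycoside",
    "C2\tother\t+\t3\t1.1\t300.1\tC10H10O2\t50\tother"))
  comp <- read_components(path)
  expect_equal(nrow(comp), 2L)
  hsya <- comp[comp$compound_id == "C1", ]
  expect_equal(hsya$ion_modes, "negative,positive")
  expect_equal(hsya$response, 250)          # max across modes
  expect_equal(hsya$peak_positive, 17L)
  expect_equal(hsya$peak_negative, 11L)
  expect_equal(read_components(path, "sum")$response[1], 350)
  expect_equal(read_components(path, "mean")$response[1], 175)
})

test_that("an empty component table with a valid header parses to zero rows", {
  path <- write_lines_tsv(components_header)
  expect_equal(nrow(read_components(path)), 0L)
})

test_that("the 79-compound fixture has the published ion-mode split", {
  comp <- read_components(phytonet_example("synthetic_components_79.tsv"))
  expect_equal(nrow(comp), 79L)
  modes <- strsplit(comp$ion_modes, ",", fixed = TRUE)
  expect_equal(sum(vapply(modes, function(m) "positive" %in% m, logical(1))), 51L)
  expect_equal(sum(vapply(modes, function(m) "negative" %in% m, logical(1))), 51L)
  expect_true(all(comp$response > 0))
})

test_that("reader errors name the offending column or row", {
  bad_col <- write_lines_tsv(c("compound_id\tname\tion_mode", "C1\tx\t+"))
  expect_error(read_components(bad_col), "response")
  bad_resp <- write_lines_tsv(c(
    components_header,
    "C1\tx\tpositive\t1\t1\t100\tCH4\thigh\tother"))
  expect_error(read_components(bad_resp), "row 1")
  expect_error(read_components(tempfile()), "not found")
  expect_error(read_predictions(write_lines_tsv(
    c("compound_id\tgene\ttanimoto", "C1\tTP53\t1.4"))), "\\[0, 1\\]")
})

test_that("GMT parsing case-folds and de-duplicates genes", {
  path <- write_lines_tsv(c("T1\tdesc\ta\tb\tA", "T2\tdesc2\tx\ty\tz"))
  terms <- read_gmt(path)
  expect_length(terms, 2L)
  expect_setequal(terms[[1]]$genes, c("A", "B"))
  expect_error(read_gmt(write_lines_tsv(c("T1\tdesc\ta", "T2\tonlydesc"))),
               "line 2")
  empty <- tempfile(); file.create(empty)
  expect_length(read_gmt(empty), 0L)
})

test_that("the packaged 34-pathway fixture loads with its module map", {
  terms <- read_gmt(phytonet_example("synthetic_pathways_34.gmt"), "kegg")
  expect_length(terms, 34L)
  expect_true(all(vapply(terms, function(t) length(t$genes) > 0, logical(1))))
})

test_that("a 3-node toy network exports to SIF with one line per edge", {
  net <- build_network(list(cmpA = "TP53"),
                       structure(list(list(term_id = "p1", term_name = "p",
                                           namespace = "kegg", genes = "TP53",
                                           module = NA_character_)),
                                 class = "gene_set_collection"))
  path <- tempfile(fileext = ".sif")
  write_network(net, path, "sif")
  expect_length(readLines(path), 2L)
})

test_that("GraphML and edge-TSV round trips preserve nodes, edges and partitions", {
  set.seed(42)
  for (i in 1:10) {
    net <- random_tripartite(n_comp = 4, n_tgt = 8, n_path = 8, p = 0.3)
    for (fmt in c("graphml", "edge_tsv")) {
      path <- tempfile(fileext = if (fmt == "graphml") ".graphml" else ".tsv")
      write_network(net, path, fmt)
      back <- read_network(path)
      expect_equal(back$nodes, net$nodes)
      expect_equal(back$edges[, c("from", "to")], net$edges[, c("from", "to")])
    }
  }
  expect_error(write_network(random_tripartite(), tempfile(), "dot"))
})

test_that("the network rebuilt from the published component table has 11 components", {
  net <- published_component_network()
  expect_equal(sum(net$nodes$partition == "component"), 11L)
  expect_true(all(c("PRKCA", "ACTB", "HK1") %in% net$nodes$node_id))
})
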