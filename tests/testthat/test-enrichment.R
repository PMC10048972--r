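test_that("hypergeometric upper tail matches closed forms and oracles", {
  expect_equal(hypergeometric_upper_tail(0, 5, 5, 20), 1.0)
  # all five query genes annotated: only one of the C(20,5) draws achieves it
  expect_equal(hypergeometric_upper_tail(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:200) {
    N <- sample(1:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_upper_tail(k, n, K, N),
                 oracle_hyper_tail(k, n, K, N), tolerance = 1e-10)
  }
  # independent library cross-check deep in the tail
  expect_equal(hypergeometric_upper_tail(40, 50, 60, 5000),
               stats::phyper(39, 60, 4940, 50, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(hypergeometric_upper_tail(6, 5, 5, 20), "min")
  expect_error(hypergeometric_upper_tail(1, 25, 5, 20), "exceed")
})

test_that("the tail probability is non-increasing in the overlap", {
  p <- vapply(0:8, function(k) hypergeometric_upper_tail(k, 10, 8, 100), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("the EASE score is the tail evaluated at k - 1", {
  expect_equal(ease_score(3, 10, 8, 100),
               hypergeometric_upper_tail(2, 10, 8, 100))
  expect_equal(ease_score(1, 10, 8, 100), 1.0)   # single-gene support scores 1
  expect_gte(ease_score(4, 10, 8, 100), hypergeometric_upper_tail(4, 10, 8, 100))
})

toy_terms <- function(...) structure(list(...), class = "gene_set_collection")
term <- function(id, genes, ns = "custom") {
  list(term_id = id, term_name = id, namespace = ns, genes = genes,
       module = NA_character_)
}

test_that("a planted enriched term ranks first", {
  set.seed(17)
  universe <- sprintf("G%03d", 1:500)
  planted <- term("planted", universe[1:12])
  decoys <- lapply(1:30, function(i)
    term(sprintf("decoy%02d", i), sample(universe, 25)))
  anns <- do.call(toy_terms, c(list(planted), decoys))
  query <- c(universe[1:10], sample(universe[100:500], 5))
  res <- enrich(query, anns)
  expect_equal(res$term_id[1], "planted")
  expect_true(res$significant[1])
  expect_true(all(diff(res$p_value) >= 0))         # sorted ascending
  expect_true(all(res$k >= 1))                     # k = 0 terms absent
  expect_false("decoy_none" %in% res$term_id)
})

test_that("a query equal to a lone term's gene set attains the minimal p", {
  anns <- toy_terms(term("only", c("A", "B", "C")))
  res <- enrich(c("A", "B", "C"), anns)
  expect_equal(res$k, 3L)
  expect_equal(res$p_value, 1.0)  # the whole universe is the term: P(X >= k) = 1
  # against a wider explicit background the same configuration is minimal
  res2 <- enrich(c("A", "B", "C"), anns,
                 enrichment_config(background = c("A", "B", "C", sprintf("X%d", 1:20))))
  expect_equal(res2$p_value, 1 / choose(23, 3), tolerance = 1e-12)
})

test_that("BH adjustment is applied within namespace and bounds raw p from above", {
  set.seed(23)
  universe <- sprintf("G%03d", 1:200)
  anns <- do.call(toy_terms, c(
    lapply(1:8, function(i) term(sprintf("k%d", i), sample(universe, 20), "kegg")),
    lapply(1:8, function(i) term(sprintf("b%d", i), sample(universe, 20), "go_bp"))))
  res <- enrich(sample(universe, 30), anns, enrichment_config(correction = "bh"))
  expect_true(all(res$p_adjusted >= res$p_value))
  for (ns in unique(res$namespace)) {
    sub <- res[res$namespace == ns, ]
    expect_equal(sub$p_adjusted,
                 stats::p.adjust(sub$p_value, "BH")[order(order(sub$p_value))],
                 tolerance = 1e-12)
    o <- order(sub$p_value)
    expect_true(all(diff(sub$p_adjusted[o]) >= -1e-12))
  }
})

test_that("a query disjoint from the background warns and returns no rows", {
  anns <- toy_terms(term("t", c("A", "B")))
  expect_warning(res <- enrich("ZZZ", anns), "background")
  expect_equal(nrow(res), 0L)
  expect_error(enrich(character(), anns), "empty")
})

test_that("module assignment labels unmapped terms as other", {
  res <- data.frame(term_id = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  expect_equal(assign_modules(res)$module, rep("other", 3))
  out <- assign_modules(res, c(t1 = "inflammation", t3 = "metabolism"))
  expect_equal(out$module, c("inflammation", "other", "metabolism"))
  expect_error(assign_modules(res, c(t1 = "inflammation", t1 = "metabolism")),
               "conflicting")
  # duplicated but consistent labels are tolerated
  expect_silent(assign_modules(res, c(t1 = "inflammation", t1 = "inflammation")))
})

test_that("the packaged 34-pathway module map yields three groups, inflammation largest", {
  terms <- read_gmt(phytonet_example("synthetic_pathways_34.gmt"), "kegg")
  mm <- utils::read.delim(phytonet_example("synthetic_pathway_modules.tsv"))
  labeled <- assign_modules(terms, stats::setNames(mm$module, mm$term_id))
  counts <- table(vapply(labeled, `[[`, character(1), "module"))
  expect_length(counts, 3L)
  expect_true(all(counts > 0))
  expect_equal(names(which.max(counts)), "inflammation")
})
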