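metrics_df <- function(ids, partition, degree) {
  data.frame(node_id = ids, partition = partition, degree = degree,
             closeness = NA_real_, betweenness = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("medians follow the standard even/odd conventions per population", {
  m <- rbind(metrics_df(sprintf("T%d", 1:5), "target", c(1, 2, 3, 4, 5)),
             metrics_df(sprintf("C%d", 1:4), "component", c(1, 2, 3, 4)))
  comp <- data.frame(compound_id = sprintf("C%d", 1:4), response = c(10, 20, 30, 40))
  thr <- compute_medians(m, NULL, comp)
  expect_equal(thr$target_degree_median, 3)
  expect_equal(thr$component_degree_median, 2.5)   # mean of middle two
  expect_equal(thr$response_median, 25)
  # literature median over topology-passing candidates (C3, C4), missing -> 0
  lit <- data.frame(compound_id = "C4", n_studies = 6L)
  thr2 <- compute_medians(m, lit, comp)
  expect_equal(thr2$literature_median, 3)          # median of {0, 6}
  expect_error(compute_medians(m[m$partition == "target", ], NULL, comp),
               "component")
  expect_error(compute_medians(m, NULL, comp[0, ]), "response")
})

test_that("hub screening keeps targets strictly above the median degree", {
  m <- metrics_df(sprintf("T%d", 1:5), "target", 1:5)
  sel <- screen_hub_targets(m)
  expect_equal(sel$gene, c("T5", "T4"))            # median 3, strict >
  none <- screen_hub_targets(metrics_df(sprintf("T%d", 1:4), "target", rep(3, 4)))
  expect_equal(nrow(none), 0L)
  # duplicated metric rows do not change the result
  dup <- screen_hub_targets(rbind(m, m))
  expect_equal(dup, sel, ignore_attr = TRUE)
})

test_that("the published hub table replays: median 6 gives 31 hubs led by PRKCA at 46", {
  hub <- published_hub_targets()
  m <- data.frame(node_id = hub$gene, partition = "target", degree = hub$degree,
                  closeness = hub$closeness, betweenness = hub$betweenness)
  expect_gt(min(hub$degree), 6)                    # smallest printed hub degree is 7
  sel <- screen_hub_targets(m, median_thresholds(target_degree_median = 6))
  expect_equal(nrow(sel), 31L)
  expect_equal(sel$gene[1], "PRKCA")
  expect_equal(sel$degree[1], 46L)
  expect_equal(sel$closeness[1], 0.46939)
  expect_equal(sel$betweenness[1], 0.13402)
})

published_thresholds <- median_thresholds(target_degree_median = 6,
                                          component_degree_median = 8,
                                          response_median = 67667,
                                          literature_median = 8)

test_that("the published quercetin evidence passes all three criteria", {
  m <- metrics_df("quercetin", "component", 12L)
  comp <- data.frame(compound_id = "quercetin", response = 233661)
  lit <- data.frame(compound_id = "quercetin", n_studies = 17L)
  out <- screen_key_components(m, published_thresholds, comp, lit)
  expect_equal(out$n_criteria, 3L)
  expect_true(out$selected)
  expect_equal(out$criteria_passed, "topology,literature,quantitation")
})

test_that("the two-of-three rule selects exactly the compounds with two criteria", {
  m <- metrics_df(c("A", "B", "C", "D"), "component", c(10L, 2L, 12L, 1L))
  comp <- data.frame(compound_id = c("A", "B", "C", "D"),
                     response = c(100000, 1000, 90000, 500))
  lit <- data.frame(compound_id = c("B", "C"), n_studies = c(9L, 20L))
  thr <- median_thresholds(component_degree_median = 8, response_median = 67667,
                           literature_median = 8)
  out <- screen_key_components(m, thr, comp, lit)
  sel <- out$compound_id[out$selected]
  expect_setequal(sel, c("A", "C"))   # A: topology+quantitation, C: all three
  expect_equal(out$n_studies[out$compound_id == "A"], 0L)  # missing literature = 0
  expect_equal(out$n_criteria[out$compound_id == "D"], 0L)
  # audit trail: every selected compound lists >= 2 fired criteria
  fired <- strsplit(out$criteria_passed[out$selected], ",")
  expect_true(all(lengths(fired) >= 2L))
})

test_that("tightening any single criterion never enlarges the selected set", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 30L
    ids <- sprintf("C%02d", 1:n)
    m <- metrics_df(ids, "component", sample(1:15, n, TRUE))
    comp <- data.frame(compound_id = ids, response = rlnorm(n, 11, 1.5))
    lit <- data.frame(compound_id = ids, n_studies = rpois(n, 3))
    thr <- median_thresholds(component_degree_median = median(m$degree),
                             response_median = median(comp$response),
                             literature_median = median(lit$n_studies))
    base <- screen_key_components(m, thr, comp, lit)
    loose_crit <- screening_criteria(literature_rule = ">=", response_rule = ">=")
    for (tight in list(screening_criteria(literature_rule = ">"),
                       screening_criteria(response_rule = ">"),
                       screening_criteria(component_degree_rule = ">"),
                       screening_criteria(min_criteria_met = 3))) {
      tightened <- screen_key_components(m, thr, comp, lit, tight)
      expect_true(all(tightened$compound_id[tightened$selected] %in%
                      base$compound_id[base$selected]))
    }
    # raising a threshold also never enlarges the selection
    thr_up <- median_thresholds(NA, thr$component_degree_median + 2,
                                thr$response_median * 2,
                                thr$literature_median + 1)
    up <- screen_key_components(m, thr_up, comp, lit)
    expect_true(all(up$compound_id[up$selected] %in%
                    base$compound_id[base$selected]))
  }
})

test_that("docking poses pass only strictly below the cutoff", {
  rec <- data.frame(compound_id = sprintf("C%02d", 1:11),
                    target_gene = "PRKCA",
                    affinity_kcal_mol = c(-7.9, rep(-8.5, 9), -4.0))
  out <- screen_docking(rec, cutoff = -7.8)
  expect_true(out$pass[1])                          # -7.9 < -7.8
  expect_equal(sum(out$pass), 10L)
  expect_equal(attr(out, "per_target_pass")$n_pass, 10L)
  boundary <- screen_docking(data.frame(compound_id = "C", target_gene = "G",
                                        affinity_kcal_mol = -5.0), cutoff = -5.0)
  expect_false(boundary$pass)
})
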