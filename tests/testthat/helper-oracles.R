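# Independent brute-force oracles used to check the package's graph
# metrics and enrichment statistic. Deliberately naive: Floyd-Warshall
# all-pairs distances, dynamic-programming shortest-path counts, and
# direct summation of hypergeometric pmf terms via choose().

oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges$from[i], edges$to[i]] <- 1
    d[edges$to[i], edges$from[i]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_closeness <- function(nodes, edges) {
  d <- oracle_distances(nodes, edges)
  vapply(seq_along(nodes), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else length(di) / sum(di)
  }, numeric(1)) |> stats::setNames(nodes)
}

# shortest-path counts sigma[s, t] by DP over the distance matrix:
# process nodes in order of distance from s, summing counts over
# predecessors one step closer
oracle_path_counts <- function(nodes, edges, d) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$from[i], nodes); b <- match(edges$to[i], nodes)
    adj[a, b] <- adj[b, a] <- TRUE
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (w in reach[order(d[s, reach])]) {
      if (w == s) next
      preds <- which(adj[, w] & d[s, ] == d[s, w] - 1)
      sigma[s, w] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  if (n < 3) return(stats::setNames(numeric(n), nodes))
  d <- oracle_distances(nodes, edges)
  sigma <- oracle_path_counts(nodes, edges, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    b[v] <- acc
  }
  stats::setNames(b * 2 / ((n - 1) * (n - 2)), nodes)
}

# P(X >= k) by direct summation of choose() products -- no logs, no
# shared code with the implementation under test
oracle_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random small tripartite network for property tests
random_tripartite <- function(n_comp = 3, n_tgt = 4, n_path = 3, p = 0.45) {
  comp <- sprintf("c%02d", seq_len(n_comp))
  tgt <- sprintf("T%02d", seq_len(n_tgt))
  pth <- sprintf("p%02d", seq_len(n_path))
  ct <- expand.grid(from = comp, to = tgt, stringsAsFactors = FALSE)
  tp <- expand.grid(from = tgt, to = pth, stringsAsFactors = FALSE)
  edges <- rbind(ct[runif(nrow(ct)) < p, ], tp[runif(nrow(tp)) < p, ])
  if (nrow(edges) == 0) edges <- ct[1, , drop = FALSE]
  nodes <- data.frame(node_id = c(comp, tgt, pth),
                      partition = rep(c("component", "target", "pathway"),
                                      c(n_comp, n_tgt, n_path)),
                      stringsAsFactors = FALSE)
  tripartite_network(nodes, edges)
}

# generate a seeded default bundle and run the full pipeline on it
run_default_bundle <- function(seed, dir = tempfile(), with_docking = FALSE,
                               cfg = synthetic_config(seed = seed)) {
  b <- generate_bundle(cfg, dir)
  pcfg <- pipeline_config(components = b$paths[["components"]],
                          predictions = b$paths[["predictions"]],
                          disease_genes = b$paths[["disease_genes"]],
                          annotations = b$paths[["annotations"]],
                          literature = b$paths[["literature"]],
                          docking = if (with_docking) b$paths[["docking"]] else NULL)
  list(bundle = b, run = run_pipeline(pcfg))
}

write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

components_header <- "compound_id\tname\tion_mode\tpeak_no\trt_min\tmz\tformula\tresponse\tclass"
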