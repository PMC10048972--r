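#' Pipeline configuration
#'
#' Collects the input paths and per-stage settings for a full screening
#' run. Only the component, prediction, disease-gene and annotation tables
#' are mandatory; literature counts default to zero studies per compound
#' and docking is skipped when no table is given.
#'
#' @param components,predictions,disease_genes,annotations Paths to the
#'   four mandatory inputs (see the `read_*` family).
#' @param literature,docking Optional paths.
#' @param selected_terms Optional path to a GMT allow-list naming the
#'   curated disease-relevant pathways used for the tripartite network;
#'   defaults to every annotation term. Curation of this list is an input,
#'   never inferred.
#' @param module_map Optional path to a TSV with columns `term_id`,
#'   `module` assigning functional-module labels.
#' @param annotation_namespace Namespace recorded for the annotation file.
#' @param target_space A [target_space_config()].
#' @param enrichment A [enrichment_config()].
#' @param criteria A [screening_criteria()].
#' @param docking_cutoff Affinity cutoff (kcal/mol) for [screen_docking()].
#' @param response_agg Response aggregation across ion modes
#'   (see [read_components()]).
#' @param out_dir Optional output directory for [render_report()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(components, predictions, disease_genes, annotations,
                            literature = NULL, docking = NULL,
                            selected_terms = NULL, module_map = NULL,
                            annotation_namespace = "custom",
                            target_space = target_space_config(),
                            enrichment = enrichment_config(),
                            criteria = screening_criteria(),
                            docking_cutoff = -5.0,
                            response_agg = "max",
                            out_dir = NULL) {
  required <- list(components = components, predictions = predictions,
                   disease_genes = disease_genes, annotations = annotations)
  for (nm in names(required)) {
    if (!is.character(required[[nm]]) || !file.exists(required[[nm]])) {
      stop(sprintf("pipeline input '%s' does not exist: %s", nm,
                   as.character(required[[nm]])[1]), call. = FALSE)
    }
  }
  for (p in c(literature, docking, selected_terms, module_map)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("pipeline input does not exist: %s", p), call. = FALSE)
    }
  }
  structure(list(paths = list(components = components, predictions = predictions,
                              disease_genes = disease_genes,
                              annotations = annotations,
                              literature = literature, docking = docking,
                              selected_terms = selected_terms,
                              module_map = module_map),
                 annotation_namespace = annotation_namespace,
                 target_space = target_space, enrichment = enrichment,
                 criteria = criteria, docking_cutoff = docking_cutoff,
                 response_agg = response_agg, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Paths are resolved relative to the YAML file's directory. Recognized
#' keys: the eight input paths of [pipeline_config()], plus nested
#' `target_space` (`tanimoto_min`), `enrichment` (`alpha`, `correction`,
#' `statistic`), `criteria` (the [screening_criteria()] fields),
#' `docking_cutoff`, `response_agg` and `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  ts <- do.call(target_space_config,
                y$target_space %||% list())
  en <- do.call(enrichment_config, y$enrichment %||% list())
  cr <- do.call(screening_criteria, y$criteria %||% list())
  pipeline_config(components = resolve(y$components),
                  predictions = resolve(y$predictions),
                  disease_genes = resolve(y$disease_genes),
                  annotations = resolve(y$annotations),
                  literature = resolve(y$literature),
                  docking = resolve(y$docking),
                  selected_terms = resolve(y$selected_terms),
                  module_map = resolve(y$module_map),
                  annotation_namespace = y$annotation_namespace %||% "custom",
                  target_space = ts, enrichment = en, criteria = cr,
                  docking_cutoff = y$docking_cutoff %||% -5.0,
                  response_agg = y$response_agg %||% "max",
                  out_dir = y$out_dir)
}

#' Run the full screening pipeline
#'
#' Executes the four analysis stages in order -- target-space overlap,
#' over-representation analysis, tripartite network construction with
#' topological metrics, and median-threshold screening (hub targets,
#' two-of-three key components, optional docking screen) -- and returns a
#' run object carrying every intermediate result, the thresholds actually
#' used (always re-computed from the inputs) and a manifest of input file
#' hashes. Identical inputs and configuration reproduce identical results.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `phytonet_run`; see [summary.phytonet_run()].
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## stage 1: target-space overlap
  overlap <- stage("overlap", {
    components <- read_components(cfg$paths$components, cfg$response_agg)
    predictions <- read_predictions(cfg$paths$predictions)
    disease <- read_disease_genes(cfg$paths$disease_genes)
    per_compound <- filter_predictions(predictions, cfg$target_space)
    disease_set <- collect_disease_genes(disease, cfg$target_space)
    res <- intersect_targets(per_compound, disease_set)
    list(components = components, result = res)
  })
  components <- overlap$components
  overlap <- overlap$result

  ## stage 2: enrichment of the overlap genes
  annotations <- read_gmt(cfg$paths$annotations, cfg$annotation_namespace)
  if (!is.null(cfg$paths$module_map)) {
    mm <- read_tsv_strict(cfg$paths$module_map)
    assert_columns(mm, c("term_id", "module"), cfg$paths$module_map)
    module_map <- stats::setNames(mm$module, mm$term_id)
  } else {
    module_map <- character()
  }
  annotations <- assign_modules(annotations, module_map)
  enrichment <- stage("enrich", {
    res <- enrich(overlap$overlap, annotations, cfg$enrichment)
    assign_modules(res, module_map)
  })

  ## stage 3: tripartite network + topology
  selected_terms <- if (!is.null(cfg$paths$selected_terms)) {
    assign_modules(read_gmt(cfg$paths$selected_terms, cfg$annotation_namespace),
                   module_map)
  } else {
    annotations
  }
  network <- stage("network", {
    term_genes <- unique(unlist(lapply(selected_terms, `[[`, "genes")))
    effective <- intersect(overlap$overlap, term_genes)
    net <- build_network(overlap$per_compound_targets, selected_terms, effective)
    list(net = net, metrics = node_metrics(net), effective_targets = sort(effective))
  })

  ## stage 4: median-threshold screening
  screening <- stage("screen", {
    literature <- if (!is.null(cfg$paths$literature)) {
      read_literature(cfg$paths$literature)
    } else NULL
    thresholds <- compute_medians(network$metrics, literature, components,
                                  cfg$criteria)
    hubs <- screen_hub_targets(network$metrics, thresholds, cfg$criteria)
    comps <- screen_key_components(network$metrics, thresholds, components,
                                   literature, cfg$criteria)
    docking <- if (!is.null(cfg$paths$docking)) {
      screen_docking(read_docking(cfg$paths$docking), cfg$docking_cutoff)
    } else NULL
    hub_enrichment <- if (nrow(hubs) > 0L) {
      enrich(hubs$gene, annotations, cfg$enrichment)
    } else empty_enrichment()
    list(thresholds = thresholds, hub_targets = hubs, components = comps,
         docking = docking, hub_enrichment = hub_enrichment)
  })

  manifest <- list(
    inputs = lapply(Filter(Negate(is.null), cfg$paths), file_md5),
    thresholds = unclass(screening$thresholds),
    network = list(n_nodes = nrow(network$net$nodes),
                   n_edges = nrow(network$net$edges),
                   nodes_per_partition = as.list(table(network$net$nodes$partition))),
    stages = c("overlap", "enrich", "network", "screen"))

  structure(list(config = cfg, components = components, overlap = overlap,
                 enrichment = enrichment, network = network$net,
                 metrics = network$metrics,
                 effective_targets = network$effective_targets,
                 thresholds = screening$thresholds,
                 hub_targets = screening$hub_targets,
                 key_components = screening$components,
                 docking = screening$docking,
                 hub_enrichment = screening$hub_enrichment,
                 manifest = manifest),
            class = "phytonet_run")
}

#' @export
print.phytonet_run <- function(x, ...) {
  cat("Integrative network-pharmacology screening run\n")
  cat(sprintf("  overlap: %d drug targets x %d disease genes -> %d shared\n",
              x$overlap$sizes[["drug_targets"]], x$overlap$sizes[["disease_genes"]],
              x$overlap$sizes[["overlap"]]))
  cat(sprintf("  network: %d nodes / %d edges", nrow(x$network$nodes),
              nrow(x$network$edges)))
  np <- table(x$network$nodes$partition)
  cat(sprintf(" (%s)\n", paste(sprintf("%d %s", as.integer(np), names(np)),
                               collapse = ", ")))
  cat(sprintf("  hub targets: %d (degree > %.6g)\n", nrow(x$hub_targets),
              x$thresholds$target_degree_median))
  cat(sprintf("  key components: %d of %d selected\n",
              sum(x$key_components$selected), nrow(x$key_components)))
  if (!is.null(x$docking)) {
    cat(sprintf("  docking: %d of %d poses pass %.1f kcal/mol\n",
                sum(x$docking$pass), nrow(x$docking), x$config$docking_cutoff))
  }
  invisible(x)
}

#' Summarize a screening run
#'
#' @param object A `phytonet_run`.
#' @param ... Unused.
#' @return A list with the thresholds, stage sizes, hub-target table and
#'   key-component audit table, printed compactly.
#' @export
summary.phytonet_run <- function(object, ...) {
  out <- list(thresholds = object$thresholds,
              sizes = object$overlap$sizes,
              network = object$manifest$network,
              hub_targets = object$hub_targets,
              key_components = object$key_components)
  class(out) <- "summary.phytonet_run"
  out
}

#' @export
print.summary.phytonet_run <- function(x, ...) {
  cat("Thresholds (all re-computed from the inputs):\n")
  thr <- x$thresholds
  cat(sprintf("  target-degree median %.6g | component-degree median %.6g | response median %.6g | literature median %.6g\n",
              thr$target_degree_median, thr$component_degree_median,
              thr$response_median, thr$literature_median))
  cat(sprintf("Hub targets (%d):\n", nrow(x$hub_targets)))
  print(utils::head(x$hub_targets, 10L))
  cat(sprintf("Key components (%d selected):\n", sum(x$key_components$selected)))
  print(utils::head(as.data.frame(x$key_components), 12L))
  invisible(x)
}

#' Diagnostic plot of a screening run
#'
#' Two base-graphics panels: the target-degree distribution with the median
#' cutoff, and the component evidence plane (degree vs response, point size
#' by study count, selected compounds filled).
#'
#' @param x A `phytonet_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phytonet_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tdeg <- x$metrics$degree[x$metrics$partition == "target"]
  graphics::hist(tdeg, breaks = "FD", col = "grey85", border = "white",
                 main = "Target degrees", xlab = "degree")
  graphics::abline(v = x$thresholds$target_degree_median, lty = 2, col = "red3")
  kc <- x$key_components
  graphics::plot(kc$degree, kc$response, log = "y",
                 pch = ifelse(kc$selected, 19, 1),
                 cex = 0.8 + sqrt(kc$n_studies) / 3,
                 xlab = "component degree", ylab = "MS response",
                 main = "Component evidence", ...)
  graphics::abline(v = x$thresholds$component_degree_median, lty = 2, col = "red3")
  graphics::abline(h = x$thresholds$response_median, lty = 2, col = "red3")
  invisible(x)
}

#' Render a report of a screening run
#'
#' Writes a Markdown summary plus machine-readable TSV tables (hub targets,
#' key-component audit trail, enrichment results, node metrics) and the
#' network in GraphML. Regenerating the report from the same run produces
#' byte-identical files.
#'
#' @param run A `phytonet_run`.
#' @param dir Output directory (created if needed); defaults to the
#'   configuration's `out_dir`.
#' @return Invisibly, the named vector of written paths.
#' @export
render_report <- function(run, dir = NULL) {
  stopifnot(inherits(run, "phytonet_run"))
  dir <- dir %||% run$config$out_dir
  if (is.null(dir)) stop("no output directory given", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.md"),
             hub_targets = file.path(dir, "hub_targets.tsv"),
             key_components = file.path(dir, "key_components.tsv"),
             enrichment = file.path(dir, "enrichment.tsv"),
             metrics = file.path(dir, "node_metrics.tsv"),
             network = file.path(dir, "network.graphml"))
  write_tsv_stable(run$hub_targets, paths[["hub_targets"]])
  write_tsv_stable(as.data.frame(run$key_components), paths[["key_components"]])
  write_tsv_stable(as.data.frame(run$enrichment), paths[["enrichment"]])
  write_tsv_stable(run$metrics, paths[["metrics"]])
  write_network(run$network, paths[["network"]], "graphml")

  thr <- run$thresholds
  np <- run$manifest$network$nodes_per_partition
  lines <- c(
    "# Network-pharmacology screening report", "",
    "## Network",
    sprintf("- %d nodes (%s components, %s targets, %s pathways), %d edges",
            run$manifest$network$n_nodes,
            np[["component"]] %||% 0, np[["target"]] %||% 0, np[["pathway"]] %||% 0,
            run$manifest$network$n_edges), "",
    "## Thresholds (re-computed from the inputs)",
    sprintf("- target-degree median: %.6g", thr$target_degree_median),
    sprintf("- component-degree median: %.6g", thr$component_degree_median),
    sprintf("- response median: %.6g", thr$response_median),
    sprintf("- literature median: %.6g", thr$literature_median), "",
    sprintf("## Hub targets (%d)", nrow(run$hub_targets)),
    md_table(run$hub_targets), "",
    sprintf("## Key components (%d selected of %d candidates)",
            sum(run$key_components$selected), nrow(run$key_components)),
    md_table(as.data.frame(run$key_components)[,
      c("compound_id", "degree", "response", "n_studies", "criteria_passed",
        "selected")]), "")
  if (!is.null(run$docking)) {
    pt <- attr(run$docking, "per_target_pass")
    lines <- c(lines,
               sprintf("## Docking screen (cutoff %.1f kcal/mol)",
                       run$config$docking_cutoff),
               md_table(pt), "")
  }
  con <- file(paths[["report"]], open = "wb")
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(paths)
}

md_table <- function(df) {
  if (nrow(df) == 0L) {
    return(c(paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
             paste0("| ", paste(rep("0 selected", 1), collapse = ""), " |")))
  }
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 6, scientific = FALSE)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
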