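#' Configuration for the synthetic evidence generator
#'
#' Describes a complete synthetic evidence bundle: an identified-component
#' table with log-normal MS responses, a heavy-tailed bipartite
#' compound-target prediction layer with planted hub compounds and hub
#' targets, multi-source disease-gene records with source-native score
#' scales, a GMT annotation collection with planted enriched terms,
#' zero-inflated overdispersed literature counts, and docking affinities.
#' The defaults mirror the statistical shape of a real herbal-extract
#' screen: ~80 identified compounds, responses spanning two orders of
#' magnitude, a handful of well-studied abundant hub compounds, and
#' disease-gene scores on the native GeneCards/DisGeNET scales.
#'
#' @param seed Integer seed; fully determines every output byte.
#' @param n_compounds Number of compounds (default 80).
#' @param n_targets Size of the predictable target universe (default 500).
#' @param n_disease_genes Number of distinct disease genes (default 900).
#' @param n_terms Number of annotation terms (default 150).
#' @param overlap_fraction Fraction of predicted target genes that also
#'   appear in the disease-gene table (default 0.2).
#' @param hub_compound_count Number of planted hub compounds (default 10).
#' @param hub_degree_multiplier Expected prediction-degree multiplier of a
#'   hub compound over the baseline (default 4).
#' @param mean_targets_per_compound Baseline mean number of predicted
#'   targets per compound; counts are negative-binomially dispersed
#'   (default 6).
#' @param hub_target_count Number of planted hub targets (default 20).
#' @param hub_target_weight Sampling weight of a hub target relative to an
#'   ordinary target when compounds draw their targets (default 10).
#' @param response_meanlog,response_sdlog Log-normal parameters of the MS
#'   response distribution (defaults 11 and 1.5).
#' @param lit_mean,lit_hub_mean Mean study counts for ordinary and hub
#'   compounds (negative binomial with size 1; defaults 3 and 10).
#' @param lit_zero_inflation Extra zero mass on ordinary compounds' study
#'   counts (default 0.3) -- many identified phytochemicals have never been
#'   studied in the disease model.
#' @param tanimoto_above_frac Fraction of prediction scores falling at or
#'   above 0.7 (default 0.65); the remainder fall below and are removed by
#'   the similarity filter.
#' @param n_planted_terms Number of annotation terms enriched for planted
#'   hub targets (default 5).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_compounds = 80L,
                             n_targets = 500L,
                             n_disease_genes = 900L,
                             n_terms = 150L,
                             overlap_fraction = 0.2,
                             hub_compound_count = 10L,
                             hub_degree_multiplier = 4,
                             mean_targets_per_compound = 6,
                             hub_target_count = 20L,
                             hub_target_weight = 10,
                             response_meanlog = 11,
                             response_sdlog = 1.5,
                             lit_mean = 3,
                             lit_hub_mean = 10,
                             lit_zero_inflation = 0.3,
                             tanimoto_above_frac = 0.65,
                             n_planted_terms = 5L) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              n_targets = as.integer(n_targets),
              n_disease_genes = as.integer(n_disease_genes),
              n_terms = as.integer(n_terms),
              overlap_fraction = overlap_fraction,
              hub_compound_count = as.integer(hub_compound_count),
              hub_degree_multiplier = hub_degree_multiplier,
              mean_targets_per_compound = mean_targets_per_compound,
              hub_target_count = as.integer(hub_target_count),
              hub_target_weight = hub_target_weight,
              response_meanlog = response_meanlog,
              response_sdlog = response_sdlog,
              lit_mean = lit_mean, lit_hub_mean = lit_hub_mean,
              lit_zero_inflation = lit_zero_inflation,
              tanimoto_above_frac = tanimoto_above_frac,
              n_planted_terms = as.integer(n_planted_terms))
  counts <- c("n_compounds", "n_targets", "n_disease_genes", "n_terms",
              "hub_compound_count", "hub_target_count", "n_planted_terms")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sprintf("configuration error: %s must be a positive count", f),
           call. = FALSE)
    }
  }
  if (cfg$hub_compound_count > cfg$n_compounds) {
    stop("configuration error: hub_compound_count exceeds n_compounds", call. = FALSE)
  }
  if (cfg$hub_target_count > cfg$n_targets) {
    stop("configuration error: hub_target_count exceeds n_targets", call. = FALSE)
  }
  if (cfg$n_planted_terms > cfg$n_terms) {
    stop("configuration error: n_planted_terms exceeds n_terms", call. = FALSE)
  }
  if (!is.numeric(cfg$overlap_fraction) || cfg$overlap_fraction <= 0 ||
      cfg$overlap_fraction > 1) {
    stop("configuration error: overlap_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic evidence bundle with planted ground truth
#'
#' Writes the six input files the screening pipeline consumes --
#' `components.tsv`, `predictions.tsv`, `disease_genes.tsv`,
#' `annotations.gmt`, `literature.tsv`, `docking.tsv` -- plus `truth.json`
#' recording the planted hub compounds, hub targets and enriched terms.
#' The same configuration (including seed) always produces byte-identical
#' files.
#'
#' Planted structure: hub compounds draw `hub_degree_multiplier` times more
#' predicted targets than the baseline and carry higher literature-study
#' counts; hub targets are over-weighted when compounds draw targets, are
#' guaranteed a curated (`tcmip`) disease-gene record, and are
#' over-represented in the planted annotation terms.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Directory to write the bundle into (created if needed).
#' @return Invisibly, a list with `dir`, `paths` (named file paths) and
#'   `truth` (the ground-truth list, also serialized to `truth.json`).
#' @export
generate_bundle <- function(cfg = synthetic_config(), out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)

  compound_ids <- sprintf("CMP%03d", seq_len(cfg$n_compounds))
  target_genes <- sprintf("TG%04d", seq_len(cfg$n_targets))
  hub_compounds <- sort(sample(compound_ids, cfg$hub_compound_count))
  hub_targets <- sort(sample(target_genes, cfg$hub_target_count))

  ## --- components: one row per (compound, ion mode) detection -----------
  is_hub <- compound_ids %in% hub_compounds
  response <- stats::rlnorm(cfg$n_compounds, cfg$response_meanlog, cfg$response_sdlog)
  both_modes <- stats::runif(cfg$n_compounds) < 0.3
  primary_mode <- ifelse(stats::runif(cfg$n_compounds) < 0.5, "positive", "negative")
  classes <- sample(c("flavonoid", "flavonoid_glycoside", "other"),
                    cfg$n_compounds, replace = TRUE, prob = c(0.40, 0.27, 0.33))
  comp_rows <- do.call(rbind, lapply(seq_len(cfg$n_compounds), function(i) {
    modes <- if (both_modes[i]) c("positive", "negative") else primary_mode[i]
    # the secondary-mode detection is slightly weaker
    resp <- if (length(modes) == 2L) c(response[i], response[i] * stats::runif(1, 0.3, 0.9))
            else response[i]
    data.frame(compound_id = compound_ids[i],
               name = sprintf("compound_%03d", i),
               ion_mode = modes,
               peak_no = sample.int(60L, length(modes)),
               rt_min = round(stats::runif(1, 0.5, 20), 2),
               mz = round(stats::runif(1, 100, 1000), 4),
               formula = sprintf("C%dH%dO%d", sample(6:30, 1), sample(6:40, 1),
                                 sample(1:16, 1)),
               response = round(resp, 0),
               class = classes[i], stringsAsFactors = FALSE)
  }))

  ## --- predictions: heavy-tailed bipartite layer with planted hubs ------
  # baseline compounds: heavy-tailed (geometric) prediction counts around
  # the configured mean; planted hubs: counts concentrated (Poisson) at
  # hub_degree_multiplier times the baseline mean, so the planted property
  # -- an elevated degree -- is actually realized per hub
  n_pred <- integer(cfg$n_compounds)
  n_pred[!is_hub] <- 1L + stats::rnbinom(sum(!is_hub), size = 1,
                                         mu = cfg$mean_targets_per_compound - 1)
  n_pred[is_hub] <- pmax(1L, stats::rpois(sum(is_hub),
    cfg$hub_degree_multiplier * cfg$mean_targets_per_compound))
  n_pred <- pmin(n_pred, cfg$n_targets)
  weights <- ifelse(target_genes %in% hub_targets, cfg$hub_target_weight, 1)
  pred_rows <- do.call(rbind, lapply(seq_len(cfg$n_compounds), function(i) {
    genes <- sample(target_genes, n_pred[i], prob = weights)
    above <- stats::runif(n_pred[i]) < cfg$tanimoto_above_frac
    tanimoto <- ifelse(above,
                       0.7 + 0.3 * stats::rbeta(n_pred[i], 2, 2),
                       0.2 + 0.49 * stats::runif(n_pred[i]))
    data.frame(compound_id = compound_ids[i], gene = genes,
               tanimoto = round(tanimoto, 3), stringsAsFactors = FALSE)
  }))

  ## --- disease genes: multi-source scored records -----------------------
  predicted_genes <- sort(unique(pred_rows$gene))
  n_from_pred <- max(1L, round(cfg$overlap_fraction * length(predicted_genes)))
  shared <- sort(unique(c(sample(predicted_genes, n_from_pred), hub_targets)))
  n_only <- max(0L, cfg$n_disease_genes - length(shared))
  disease_genes <- c(shared, sprintf("DZ%04d", seq_len(n_only)))
  dg_rows <- do.call(rbind, lapply(disease_genes, function(g) {
    k <- 1L + stats::rbinom(1L, 2L, 0.3)
    src <- sample(c("genecards", "disgenet", "tcmip"), k, prob = c(0.45, 0.45, 0.1))
    if (g %in% hub_targets && !"tcmip" %in% src) src <- c(src, "tcmip")
    score <- vapply(src, function(s) switch(s,
      genecards = round(stats::runif(1, 0, 30), 2),
      disgenet = round(stats::runif(1, 0, 0.5), 3),
      tcmip = NA_real_), numeric(1))
    data.frame(gene = g, source = src, score = score, stringsAsFactors = FALSE)
  }))

  ## --- annotations: GMT with planted hub-enriched terms -----------------
  gene_pool <- c(target_genes, disease_genes)
  planted_terms <- sprintf("PATH%04d", seq_len(cfg$n_planted_terms))
  ann <- lapply(seq_len(cfg$n_terms), function(j) {
    id <- sprintf("PATH%04d", j)
    size <- sample(10:40, 1)
    genes <- if (j <= cfg$n_planted_terms) {
      n_hub <- min(length(hub_targets), max(2L, round(0.6 * size)))
      unique(c(sample(hub_targets, n_hub), sample(gene_pool, size - n_hub)))
    } else {
      unique(sample(gene_pool, size))
    }
    list(term_id = id, term_name = sprintf("synthetic pathway %d", j),
         namespace = "custom", genes = sort(genes), module = NA_character_)
  })
  ann <- structure(ann, class = "gene_set_collection")

  ## --- literature: zero-inflated overdispersed counts -------------------
  lit <- integer(cfg$n_compounds)
  lit[is_hub] <- stats::rnbinom(sum(is_hub), size = 1, mu = cfg$lit_hub_mean)
  n_ord <- sum(!is_hub)
  ord <- stats::rnbinom(n_ord, size = 1, mu = cfg$lit_mean)
  ord[stats::runif(n_ord) < cfg$lit_zero_inflation] <- 0L
  lit[!is_hub] <- ord
  lit_rows <- data.frame(compound_id = compound_ids, n_studies = lit,
                         stringsAsFactors = FALSE)

  ## --- docking: favorable poses for hubs, diffuse background ------------
  dock_targets <- hub_targets[seq_len(min(3L, length(hub_targets)))]
  dock_hub <- expand.grid(compound_id = hub_compounds, target_gene = dock_targets,
                          stringsAsFactors = FALSE)
  dock_hub$affinity_kcal_mol <- round(stats::rnorm(nrow(dock_hub), -7, 1), 1)
  n_bg <- min(30L, cfg$n_compounds)
  dock_bg <- data.frame(compound_id = sample(compound_ids, n_bg, replace = TRUE),
                        target_gene = sample(target_genes, n_bg, replace = TRUE),
                        stringsAsFactors = FALSE)
  dock_bg$affinity_kcal_mol <- round(stats::rnorm(n_bg, -4.5, 1.5), 1)
  dock_rows <- unique(rbind(dock_hub, dock_bg))

  paths <- c(components = file.path(out_dir, "components.tsv"),
             predictions = file.path(out_dir, "predictions.tsv"),
             disease_genes = file.path(out_dir, "disease_genes.tsv"),
             annotations = file.path(out_dir, "annotations.gmt"),
             literature = file.path(out_dir, "literature.tsv"),
             docking = file.path(out_dir, "docking.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_tsv_stable(comp_rows, paths[["components"]])
  write_tsv_stable(pred_rows, paths[["predictions"]])
  dg_rows$score[is.na(dg_rows$score)] <- ""
  write_tsv_stable(dg_rows, paths[["disease_genes"]])
  write_gmt(ann, paths[["annotations"]])
  write_tsv_stable(lit_rows, paths[["literature"]])
  write_tsv_stable(dock_rows, paths[["docking"]])

  truth <- list(planted_hub_compounds = hub_compounds,
                planted_hub_targets = hub_targets,
                planted_enriched_terms = planted_terms,
                universe = list(compounds = compound_ids,
                                targets = target_genes,
                                terms = sprintf("PATH%04d", seq_len(cfg$n_terms))))
  jsonlite::write_json(truth, paths[["truth"]], pretty = TRUE)

  invisible(list(dir = out_dir, paths = paths, truth = truth, config = cfg))
}

#' Score recovery of planted structure
#'
#' Compares a selection (e.g. the compounds selected by the two-of-three
#' screen, or the screened hub targets) against the generator's planted
#' ground truth, by exact set arithmetic.
#'
#' @param selection Named list with any of `hub_compounds`, `hub_targets`,
#'   `enriched_terms`: character vectors of selected ids.
#' @param truth Ground truth from [generate_bundle()] (the `truth` element,
#'   or a path to `truth.json`).
#' @return Data frame with one row per evaluated class: `class`,
#'   `n_selected`, `n_truth`, `n_hit`, `precision` (NA when nothing was
#'   selected), `recall`.
#' @export
evaluate_recovery <- function(selection, truth) {
  if (is.character(truth) && length(truth) == 1L) {
    truth <- jsonlite::read_json(truth, simplifyVector = TRUE)
  }
  classes <- c(hub_compounds = "planted_hub_compounds",
               hub_targets = "planted_hub_targets",
               enriched_terms = "planted_enriched_terms")
  universes <- c(hub_compounds = "compounds", hub_targets = "targets",
                 enriched_terms = "terms")
  rows <- lapply(names(selection), function(cls) {
    if (!cls %in% names(classes)) {
      stop(sprintf("unknown selection class '%s'", cls), call. = FALSE)
    }
    sel <- unique(as.character(selection[[cls]]))
    tru <- unique(as.character(truth[[classes[[cls]]]]))
    uni <- truth$universe[[universes[[cls]]]]
    if (!is.null(uni)) {
      alien <- setdiff(sel, uni)
      if (length(alien) > 0L) {
        stop(sprintf("selection/truth id mismatch in class '%s': %s",
                     cls, paste(utils::head(alien, 3L), collapse = ", ")),
             call. = FALSE)
      }
    }
    hit <- length(intersect(sel, tru))
    data.frame(class = cls, n_selected = length(sel), n_truth = length(tru),
               n_hit = hit,
               precision = if (length(sel) == 0L) NA_real_ else hit / length(sel),
               recall = if (length(tru) == 0L) NA_real_ else hit / length(tru),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
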