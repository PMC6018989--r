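# End-to-end orchestration of the screen analysis.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the reference
#' defaults: score threshold 3 SD, constriction-degree threshold 0.15,
#' consensus threshold 0.9 over the embedding maps, DBSCAN minPoints 3,
#' bootstrap support 0.7.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param score_threshold Absolute score flagging cutoff.
#' @param constriction_threshold Constriction-degree threshold.
#' @param n_maps Embeddings for the consensus islands.
#' @param perplexity t-SNE perplexity.
#' @param eps DBSCAN radius; `NULL` tunes it over `eps_grid`.
#' @param eps_grid Candidate radii for [tune_dbscan()].
#' @param min_points DBSCAN minPoints.
#' @param co_threshold Consensus co-clustering threshold.
#' @param n_boot,support_threshold Network bootstrap parameters.
#' @param min_cells Low-population flagging threshold.
#' @param correct_time_bias Recentre timing features against the
#'   wild-type imaging-time trend? Off by default: the synthetic screens
#'   carry no temporal drift.
#' @param run_islands,run_network Stage toggles.
#' @param network_features Feature set for network inference (the
#'   screened non-collinear set).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            score_threshold = 3,
                            constriction_threshold = 0.15,
                            n_maps = 100,
                            perplexity = 30,
                            eps = NULL,
                            eps_grid = c(2, 3, 4, 5, 6, 8, 10, 12),
                            min_points = 3,
                            co_threshold = 0.9,
                            n_boot = 200,
                            support_threshold = 0.7,
                            min_cells = 30,
                            correct_time_bias = FALSE,
                            run_islands = TRUE,
                            run_network = TRUE,
                            network_features = c(
                              "mean_length", "mean_width", "mean_area",
                              "mean_nucleoid_area", "alpha_max", "od_max",
                              "rel_t_nuc", "rel_t_const", "rho_cd",
                              "cdn_c0")) {
  cfg <- as.list(environment())
  if (cfg$score_threshold < 0 || cfg$co_threshold <= 0 ||
      cfg$co_threshold > 1 || cfg$support_threshold < 0 ||
      cfg$support_threshold > 1) {
    abort("a pipeline threshold is out of range.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the screen analysis end to end
#'
#' Executes the stages in dependency order: growth-curve fitting, strain
#' feature extraction, plate-bias correction, scoring against the
#' wild-type replicates, phenotype flagging, consensus-island detection
#' on the flagged strains plus the wild-type controls, optional
#' categorical enrichment of the flagged sets, and mutual-information
#' network inference over the non-collinear feature set. Every stochastic
#' stage derives its seed from `config$seed`, so reruns are reproducible.
#'
#' @param cells Cell table for all strains (see [generate_screen()]).
#' @param growth Long growth-curve table.
#' @param wt_ids Wild-type replicate ids (scores are undefined without
#'   them).
#' @param plate_map Optional `strain_id` / `plate` table for plate-bias
#'   correction.
#' @param annotations Optional `id` / `term` annotation tibble; enables
#'   enrichment of the flagged strain sets.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, features.csv,
#'   scores.csv, islands.csv, edges.csv and a JSON run manifest are
#'   written there.
#' @return A list of class `pipeline_result` with elements `features`,
#'   `scores`, `flags`, `growth_fits`, `islands` (partition or `NULL`),
#'   `embeds`, `enrichment`, `network`, `config`.
#' @export
run_pipeline <- function(cells, growth, wt_ids, plate_map = NULL,
                         annotations = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  if (length(wt_ids) < 10) {
    abort("missing or insufficient wild-type replicates: scores are undefined without >= 10 WT rows.")
  }

  growth_fits <- fit_growth_curves(growth)
  features <- screen_features(
    cells, growth_fits,
    constriction_threshold = config$constriction_threshold,
    min_cells = config$min_cells)

  if (!is.null(plate_map)) {
    features <- correct_plate_bias(features, plate_map, wt_ids = wt_ids)
  }
  if (isTRUE(config$correct_time_bias) && "image_time_min" %in% names(cells)) {
    times <- cells |>
      group_by(.data$strain_id) |>
      summarise(image_time_min = .data$image_time_min[1], .groups = "drop")
    features <- correct_time_bias(features, times, wt_ids)
  }

  scores <- compute_scores(features, wt_ids)
  flags <- flag_phenotypes(scores, threshold = config$score_threshold)

  islands <- NULL; embeds <- NULL
  if (isTRUE(config$run_islands)) {
    hit_ids <- unique(unlist(flags$strains))
    sel <- scores$strain_id %in% c(hit_ids, wt_ids)
    sub <- scores[sel, , drop = FALSE]
    x <- score_matrix_values(as_tibble(sub))
    x[is.na(x)] <- 0 # missing-coded features sit at the WT reference
    # repeated-embedding consensus is unstable below a few dozen points
    if (nrow(x) >= 20) {
      embeds <- embed_consensus(
        cbind(tibble(strain_id = rownames(x)), as_tibble(x)),
        n_maps = config$n_maps, perplexity = config$perplexity,
        seed = derive_seed(config$seed, 1))
      eps <- config$eps
      if (is.null(eps)) {
        eps <- tune_dbscan(embeds, wt_ids, eps_grid = config$eps_grid,
                           min_points = config$min_points,
                           co_threshold = config$co_threshold)$eps
      }
      islands <- consensus_islands(embeds, eps = eps,
                                   min_points = config$min_points,
                                   co_threshold = config$co_threshold)
    }
  }

  enrichment <- NULL
  if (!is.null(annotations)) {
    universe <- unique(scores$strain_id)
    enrichment <- imap(flags$strains, function(set, cls) {
      if (length(set) == 0) return(NULL)
      term_enrichment(set, universe, annotations, adjust = "BH")
    })
  }

  network <- NULL
  if (isTRUE(config$run_network)) {
    feat_cols <- intersect(config$network_features, names(scores))
    x <- as_tibble(scores)[, c("strain_id", feat_cols)]
    x <- x[complete.cases(x), , drop = FALSE]
    if (nrow(x) >= 30 && length(feat_cols) >= 3) {
      screened <- belsley_screen(x)
      keep <- c("strain_id", screened$retained)
      network <- bootstrap_network(
        x[, keep], n_boot = config$n_boot,
        support_threshold = config$support_threshold,
        seed = derive_seed(config$seed, 2))
    }
  }

  result <- structure(
    list(features = features, scores = scores, flags = flags,
         growth_fits = growth_fits, islands = islands, embeds = embeds,
         enrichment = enrichment, network = network, config = config),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$features, file.path(out_dir, "features.csv"))
  readr::write_csv(as_tibble(result$scores), file.path(out_dir, "scores.csv"))
  readr::write_csv(result$growth_fits, file.path(out_dir, "growthfits.csv"))
  if (!is.null(result$islands)) {
    readr::write_csv(result$islands$assignment,
                     file.path(out_dir, "islands.csv"))
  }
  if (!is.null(result$network)) {
    readr::write_csv(result$network$edges, file.path(out_dir, "edges.csv"))
  }
  cfg <- unclass(result$config)
  manifest <- list(
    config = cfg[order(names(cfg))],
    config_hash = rlang::hash(cfg[order(names(cfg))]),
    seed = result$config$seed,
    n_strains = nrow(result$features),
    timestamp = "deterministic-output")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d strains, %d features scored\n", nrow(x$features),
              ncol(as_tibble(x$scores)) - 1))
  pc <- x$flags$per_class
  cat("  flagged strains:",
      paste(pc$class, pc$n_flagged, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$islands)) {
    cat(sprintf("  %d consensus islands\n", max(x$islands$assignment$island)))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d retained edges\n",
                sum(x$network$edges$retained)))
  }
  invisible(x)
}
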