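# Plain-text interchange formats: per-cell tables, growth curves,
# annotations, ground truth.

cells_schema <- c(
  "strain_id", "plate", "well", "image_time_min", "od_imaging", "cell_id",
  "length_um", "width_um", "area_um2", "perimeter_um",
  "constriction_degree", "division_ratio", "nucleoid_count",
  "nucleoid_area_um2", "nucleoid_constriction_degree",
  "nucleoid_variability", "nucleoid_intensity",
  "dapi_total", "phase_mean", "intracell_width_cv", "contour_phase_mean"
)

#' Read / write screen data files
#'
#' CSV readers and writers for the screen's interchange tables: per-cell
#' measurements (`cells.csv`), growth curves (`growth.csv`, long format)
#' and id-term annotations (`annotations.tsv`). `write_screen()` writes a
#' whole [generate_screen()] result (cells, growth, and the ground truth
#' as JSON) into a directory.
#'
#' @param path File path (directory for `write_screen()`).
#' @param cells,growth Tibbles to write.
#' @return Readers return tibbles; writers return the path invisibly.
#' @export
read_cells <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, setdiff(cells_schema, c("plate", "well", "image_time_min",
                                            "od_imaging")), "cells.csv")
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  cols <- intersect(cells_schema, names(cells))
  readr::write_csv(cells[, cols], path)
  invisible(path)
}

#' @rdname read_cells
#' @export
read_growth <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("strain_id", "time_min", "od600"), "growth.csv")
  df
}

#' @rdname read_cells
#' @export
write_growth <- function(growth, path) {
  readr::write_csv(growth[, c("strain_id", "time_min", "od600")], path)
  invisible(path)
}

#' @rdname read_cells
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("id", "term"), "annotations.tsv")
  df
}

#' @rdname read_cells
#' @param screen A [generate_screen()] result.
#' @param dir Output directory (created if needed).
#' @export
write_screen <- function(screen, dir) {
  if (!inherits(screen, "synthetic_screen")) {
    abort("`screen` must come from generate_screen().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cells(screen$cells, file.path(dir, "cells.csv"))
  write_growth(screen$growth, file.path(dir, "growth.csv"))
  truth <- screen$truth
  jsonlite::write_json(
    list(seed = truth$seed,
         wt_ids = truth$wt_ids,
         plate_map = truth$plate_map,
         strain_info = truth$strain_info,
         wt_sd = as.list(truth$wt_sd),
         plate_bias = as.list(truth$plate_bias)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replication summary of a published score table
#'
#' Given a strain-by-feature table of wild-type-referenced scores (for
#' example the deposited score dataset of a published screen, mapped onto
#' this package's feature names), computes the headline summary numbers:
#' the count of strains with at least one absolute score >= `threshold`
#' in each feature class, and Pearson correlations between selected score
#' columns (scores are affine transforms of the corrected features, so
#' correlations computed on scores equal those on the features).
#'
#' @param scores Data frame with `strain_id` and score columns named as
#'   in [feature_classes()].
#' @param threshold Absolute score cutoff (default 3).
#' @param pairs Named list of column pairs to correlate.
#' @return A list with `counts` (tibble class / n_flagged) and
#'   `correlations` (tibble pair / rho / n).
#' @export
replication_summary <- function(scores, threshold = 3,
                                pairs = list(
                                  area_vs_nucleoid = c("mean_area", "mean_nucleoid_area"),
                                  timing_vs_timing = c("rel_t_nuc", "rel_t_const"),
                                  length_vs_width = c("mean_length", "mean_width"),
                                  nucleoid_vs_t_nuc = c("mean_nucleoid_area", "rel_t_nuc"))) {
  classes <- feature_classes()
  feat_cols <- intersect(names(classes), names(scores))
  counts <- lapply(split(feat_cols, classes[feat_cols]), function(fc) {
    hit <- rep(FALSE, nrow(scores))
    for (f in fc) hit <- hit | (!is.na(scores[[f]]) & abs(scores[[f]]) >= threshold)
    sum(hit)
  })
  cors <- list_rbind(imap(pairs, function(cols, nm) {
    ok <- complete.cases(scores[, cols])
    tibble(pair = nm,
           rho = cor(scores[[cols[1]]][ok], scores[[cols[2]]][ok]),
           n = sum(ok))
  }))
  list(counts = tibble(class = names(counts),
                       n_flagged = unlist(counts, use.names = FALSE)),
       correlations = cors)
}
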