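# Strain-level phenotyping: population summaries, plate-bias correction,
# and robust wild-type-referenced scores.

morph_feature_names <- c(
  "mean_length", "cv_length", "mean_width", "cv_width", "mean_area",
  "cv_area", "mean_perimeter", "cv_perimeter", "mean_volume", "cv_volume",
  "mean_surface", "cv_surface", "mean_sv_ratio", "cv_sv_ratio",
  "mean_aspect_ratio", "cv_aspect_ratio", "mean_circularity",
  "cv_circularity", "cv_division_ratio"
)
cellcycle_feature_names <- c(
  "rel_t_nuc", "rel_t_const", "mean_nucleoid_area", "rho_cd", "cdn_c0"
)
growth_feature_names <- c("alpha_max", "od_max")

#' Feature classes of the screen
#'
#' Named character vector mapping each of the 26 strain-level features to
#' its class: 19 morphological, 5 cell-cycle, 2 growth.
#' @return Named character vector (names = features, values = class).
#' @export
feature_classes <- function() {
  c(setNames(rep("morphological", length(morph_feature_names)),
             morph_feature_names),
    setNames(rep("cellcycle", length(cellcycle_feature_names)),
             cellcycle_feature_names),
    setNames(rep("growth", length(growth_feature_names)),
             growth_feature_names))
}

#' Summarize one strain's cell population into its feature vector
#'
#' Computes the 19 morphological features (mean and CV of length, width,
#' area, perimeter, spherocylinder volume, surface area, surface-to-volume
#' ratio, aspect ratio and circularity, plus the CV of the division
#' ratio) and the 5 cell-cycle features ([cellcycle_features()]). The
#' division-ratio set is augmented with its complements `{r, 1 - r}`
#' before taking the CV: pole identity is unknown, so the mean division
#' ratio is 0.5 by construction and only its spread is informative.
#'
#' @param table One strain's cell table.
#' @param growth_fit Optional one-row tibble (or `gompertz_fit` glance)
#'   with `alpha_max` and `od_max` to append as the two growth features.
#' @param constriction_threshold Constriction-degree threshold for the
#'   constriction-timing fraction.
#' @param min_cells Populations below this size are flagged `low_n`.
#' @return One-row tibble with the features plus `strain_id`, `n_cells`,
#'   `low_n`.
#' @export
strain_features <- function(table, growth_fit = NULL,
                            constriction_threshold = 0.15,
                            min_cells = 30) {
  check_columns(table, c("length_um", "width_um", "constriction_degree",
                         "division_ratio"), "cell table")
  if (nrow(table) == 0) abort("empty cell table.")

  geom <- spherocylinder_geometry(table$length_um, table$width_um)
  constr <- table$constriction_degree > 0
  dr <- table$division_ratio[constr & !is.na(table$division_ratio)]
  cv_dr <- if (length(dr) >= 2) {
    aug <- c(dr, 1 - dr)
    stats::sd(aug) / mean(aug)
  } else {
    NA_real_
  }

  morph <- tibble(
    mean_length = mean(table$length_um), cv_length = cv(table$length_um),
    mean_width = mean(table$width_um), cv_width = cv(table$width_um),
    mean_area = mean(geom$area_um2), cv_area = cv(geom$area_um2),
    mean_perimeter = mean(geom$perimeter_um),
    cv_perimeter = cv(geom$perimeter_um),
    mean_volume = mean(geom$volume_um3), cv_volume = cv(geom$volume_um3),
    mean_surface = mean(geom$surface_um2), cv_surface = cv(geom$surface_um2),
    mean_sv_ratio = mean(geom$sv_ratio), cv_sv_ratio = cv(geom$sv_ratio),
    mean_aspect_ratio = mean(geom$aspect_ratio),
    cv_aspect_ratio = cv(geom$aspect_ratio),
    mean_circularity = mean(geom$circularity),
    cv_circularity = cv(geom$circularity),
    cv_division_ratio = cv_dr
  )
  cc <- cellcycle_features(table,
                           constriction_threshold = constriction_threshold)
  out <- bind_cols(
    tibble(strain_id = table$strain_id[1], n_cells = nrow(table),
           low_n = nrow(table) < min_cells),
    morph, cc)
  if (!is.null(growth_fit)) {
    out$alpha_max <- growth_fit$alpha_max[1]
    out$od_max <- growth_fit$od_max[1]
  }
  out
}

#' Strain-level feature matrix for a whole screen
#'
#' Applies [strain_features()] per strain and joins the growth features
#' from [fit_growth_curves()].
#'
#' @param cells Cell table covering all strains (column `strain_id`).
#' @param growth_fits Output of [fit_growth_curves()] (optional).
#' @inheritParams strain_features
#' @return Tibble, one row per strain, 26 feature columns plus
#'   `strain_id`, `n_cells`, `low_n`.
#' @export
screen_features <- function(cells, growth_fits = NULL,
                            constriction_threshold = 0.15, min_cells = 30) {
  feats <- cells |>
    group_by(.data$strain_id) |>
    dplyr::group_modify(function(df, key) {
      strain_features(mutate(df, strain_id = key$strain_id),
                      constriction_threshold = constriction_threshold,
                      min_cells = min_cells) |>
        select(-"strain_id")
    }) |>
    ungroup()
  if (!is.null(growth_fits)) {
    feats <- left_join(
      feats,
      select(growth_fits, "strain_id", "alpha_max", "od_max"),
      by = "strain_id")
  }
  feats
}

#' Correct plate-to-plate bias in a feature matrix
#'
#' For each plate and feature, rescales values so the plate median equals
#' the parental (wild-type) median: multiplicatively for strictly
#' positive features, by shift for signed features (correlations and
#' other sign-carrying quantities).
#'
#' @param features Feature tibble with `strain_id` and feature columns.
#' @param plate_map Tibble `strain_id`, `plate`.
#' @param parental_medians Named vector of the parental strain's feature
#'   medians; defaults to the medians of `wt_ids` rows.
#' @param wt_ids Wild-type strain ids (used when `parental_medians` is
#'   not given).
#' @param signed_features Features corrected by shift rather than scale.
#' @return The corrected feature tibble (same shape).
#' @export
correct_plate_bias <- function(features, plate_map, parental_medians = NULL,
                               wt_ids = NULL,
                               signed_features = "rho_cd") {
  check_columns(plate_map, c("strain_id", "plate"), "plate map")
  feat_cols <- intersect(names(feature_classes()), names(features))
  if (is.null(parental_medians)) {
    if (is.null(wt_ids)) abort("supply `parental_medians` or `wt_ids`.")
    wt_rows <- features$strain_id %in% wt_ids
    if (!any(wt_rows)) abort("no wild-type rows found.")
    parental_medians <- vapply(feat_cols, function(f) {
      stats::median(features[[f]][wt_rows], na.rm = TRUE)
    }, numeric(1))
  }
  df <- left_join(features, select(plate_map, "strain_id", "plate"),
                  by = "strain_id")
  for (f in feat_cols) {
    target <- parental_medians[[f]]
    if (is.null(target) || is.na(target)) next
    for (p in unique(df$plate)) {
      rows <- which(df$plate == p)
      med <- stats::median(df[[f]][rows], na.rm = TRUE)
      if (is.na(med)) next
      if (f %in% signed_features || target <= 0 || med <= 0) {
        df[[f]][rows] <- df[[f]][rows] - med + target
      } else {
        df[[f]][rows] <- df[[f]][rows] * target / med
      }
    }
  }
  select(df, -"plate")
}

#' Recentre features against an imaging-time trend in the wild type
#'
#' Fraction-derived features can drift with the time at which a plate was
#' imaged. This correction fits a running-median trend of each feature
#' against imaging time on the wild-type replicates and removes it from
#' all strains, restoring the overall wild-type median.
#'
#' @param features Feature tibble with `strain_id` and feature columns.
#' @param times Tibble `strain_id`, `image_time_min`.
#' @param wt_ids Wild-type strain ids.
#' @param cols Features to correct (default: the cell-cycle timings).
#' @param span Loess span of the trend fit.
#' @return Corrected feature tibble.
#' @export
correct_time_bias <- function(features, times, wt_ids,
                              cols = c("rel_t_nuc", "rel_t_const"),
                              span = 0.75) {
  check_columns(times, c("strain_id", "image_time_min"), "times")
  df <- left_join(features, times, by = "strain_id")
  wt <- df$strain_id %in% wt_ids
  if (sum(wt) < 10) abort("need >= 10 wild-type rows for the trend fit.")
  for (f in intersect(cols, names(df))) {
    fit <- stats::loess(df[[f]][wt] ~ df$image_time_min[wt],
                        span = span, degree = 1,
                        control = stats::loess.control(surface = "direct"))
    trend <- predict(fit, newdata = df$image_time_min)
    trend[is.na(trend)] <- mean(df[[f]][wt], na.rm = TRUE)
    df[[f]] <- df[[f]] - trend + stats::median(df[[f]][wt], na.rm = TRUE)
  }
  select(df, -"image_time_min")
}

#' Transform features into robust wild-type-referenced scores
#'
#' Each feature value is converted to
#' `s = 1.35 * (F - median(F_WT)) / iqr(F_WT)`. Because the interquartile
#' range of normal data equals 1.35 standard deviations, the scores read
#' as "standard deviations away from the wild-type median" while staying
#' robust to outliers. Features with zero wild-type iqr are dropped with
#' a warning.
#'
#' @param features Feature tibble with `strain_id` and feature columns.
#' @param wt_ids Wild-type strain ids (>= 10 rows required).
#' @return An object of class `score_matrix`: a tibble of scores with the
#'   per-feature `wt_median` / `wt_iqr` used stored as attributes
#'   (`wt_stats`) together with `wt_ids`.
#' @export
compute_scores <- function(features, wt_ids) {
  feat_cols <- intersect(names(feature_classes()), names(features))
  wt_rows <- features$strain_id %in% wt_ids
  if (sum(wt_rows) < 10) abort("need >= 10 wild-type rows to compute scores.")
  out <- features[, c("strain_id", feat_cols)]
  stats_list <- list()
  dropped <- character(0)
  for (f in feat_cols) {
    m <- stats::median(features[[f]][wt_rows], na.rm = TRUE)
    iq <- stats::IQR(features[[f]][wt_rows], na.rm = TRUE)
    if (!is.finite(iq) || iq == 0) {
      dropped <- c(dropped, f)
      out[[f]] <- NULL
      next
    }
    out[[f]] <- 1.35 * (features[[f]] - m) / iq
    stats_list[[f]] <- tibble(feature = f, wt_median = m, wt_iqr = iq)
  }
  if (length(dropped)) {
    warn(paste("dropped features with zero wild-type iqr:",
               paste(dropped, collapse = ", ")))
  }
  structure(out,
            wt_stats = list_rbind(stats_list),
            wt_ids = wt_ids,
            class = c("score_matrix", class(out)))
}

#' Flag strains with extreme phenotypes
#'
#' Counts and lists, per feature and per feature class, the strains with
#' at least one absolute score at or beyond the threshold. The reference
#' screen's conservative threshold is 3 wild-type standard deviations.
#'
#' @param scores A [compute_scores()] result (wild-type rows are excluded
#'   from the counts).
#' @param threshold Absolute score cutoff (default 3).
#' @param include_wt Keep wild-type replicates in the counts?
#' @return A list with `per_feature` (tibble feature/class/n_flagged),
#'   `per_class` (tibble class/n_flagged) and `strains` (named list of
#'   flagged strain ids per class).
#' @export
flag_phenotypes <- function(scores, threshold = 3, include_wt = FALSE) {
  classes <- feature_classes()
  feat_cols <- intersect(names(classes), names(scores))
  df <- as_tibble(scores)
  if (!include_wt) {
    df <- filter(df, !(.data$strain_id %in% attr(scores, "wt_ids")))
  }
  per_feature <- list_rbind(lapply(feat_cols, function(f) {
    tibble(feature = f, class = unname(classes[[f]]),
           n_flagged = sum(abs(df[[f]]) >= threshold, na.rm = TRUE))
  }))
  strain_sets <- lapply(split(feat_cols, classes[feat_cols]), function(fc) {
    hit <- rep(FALSE, nrow(df))
    for (f in fc) hit <- hit | (!is.na(df[[f]]) & abs(df[[f]]) >= threshold)
    df$strain_id[hit]
  })
  per_class <- tibble(class = names(strain_sets),
                      n_flagged = vapply(strain_sets, length, integer(1)))
  list(per_feature = per_feature, per_class = per_class,
       strains = strain_sets)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d strains x %d features (%d WT replicates)\n",
              nrow(x), ncol(x) - 1, length(attr(x, "wt_ids"))))
  NextMethod()
}
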