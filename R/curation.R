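# Contour curation: a linear max-margin classifier over 16 robustly
# normalized per-cell features separates well-detected cells from
# segmentation artefacts.

curation_feature_names <- c(
  "length", "width", "area", "volume", "perimeter", "constriction_degree",
  "division_ratio", "integrated_phase", "integrated_dapi",
  "mean_contour_phase", "intracell_width_variability", "nucleoid_area",
  "nucleoid_variability", "circularity", "nucleoid_intensity",
  "nucleoid_count"
)

#' Extract the 16 per-cell contour-quality features
#'
#' Builds the feature matrix used by contour curation: cell dimensions,
#' spherocylinder volume, circularity (`4 * pi * A / P^2`), constriction
#' degree, division ratio (imputed at 0.5 when absent, with a
#' missingness indicator folded into the stored normalization),
#' integrated and contour intensities, and nucleoid measurements. Each
#' feature is robustly standardized (median / iqr) and the statistics are
#' stored so the identical transform can be applied at prediction time.
#'
#' @param table A cell table (see [generate_cell_population()] for the
#'   column schema).
#' @param stats Optional normalization statistics from a previous call
#'   (as stored in a [train_curation_model()] model); if `NULL` they are
#'   fitted on `table`.
#' @return A list with `x` (numeric matrix, cells x 16, normalized),
#'   `dr_missing` (logical vector) and `stats` (tibble of per-feature
#'   median and iqr).
#' @export
extract_contour_features <- function(table, stats = NULL) {
  required <- c("length_um", "width_um", "area_um2", "perimeter_um",
                "constriction_degree", "division_ratio", "phase_mean",
                "dapi_total", "contour_phase_mean", "intracell_width_cv",
                "nucleoid_area_um2", "nucleoid_variability",
                "nucleoid_intensity", "nucleoid_count")
  check_columns(table, required, "cell table")

  geom <- spherocylinder_geometry(table$length_um, table$width_um)
  dr_missing <- is.na(table$division_ratio)
  dr <- ifelse(dr_missing, 0.5, table$division_ratio)

  raw <- cbind(
    length = table$length_um,
    width = table$width_um,
    area = table$area_um2,
    volume = geom$volume_um3,
    perimeter = table$perimeter_um,
    constriction_degree = table$constriction_degree,
    division_ratio = dr,
    integrated_phase = table$phase_mean * table$area_um2,
    integrated_dapi = table$dapi_total,
    mean_contour_phase = table$contour_phase_mean,
    intracell_width_variability = table$intracell_width_cv,
    nucleoid_area = table$nucleoid_area_um2,
    nucleoid_variability = table$nucleoid_variability,
    circularity = 4 * pi * table$area_um2 / table$perimeter_um^2,
    nucleoid_intensity = table$nucleoid_intensity,
    nucleoid_count = as.numeric(table$nucleoid_count)
  )
  raw <- raw[, curation_feature_names, drop = FALSE]

  if (is.null(stats)) {
    med <- apply(raw, 2, stats::median)
    iqr <- apply(raw, 2, stats::IQR)
    iqr[iqr < 1e-9] <- 1 # constant feature: leave centred, unscaled
    stats <- tibble(feature = colnames(raw), median = med, iqr = iqr)
  }
  x <- sweep(sweep(raw, 2, stats$median), 2, stats$iqr, "/")
  x <- cbind(x, dr_missing = as.numeric(dr_missing))
  x[!is.finite(x)] <- 0
  list(x = x, dr_missing = dr_missing, stats = stats)
}

#' Train the contour-curation classifier
#'
#' A linear support-vector machine over the 16 normalized contour
#' features, with inverse-class-frequency weights (the screen's headline
#' metric is the balanced classification rate) and the regularization
#' cost chosen by internal k-fold cross-validation over a small grid.
#'
#' @param table Labelled cell table.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = good contour.
#' @param k Folds for the internal cost search.
#' @param costs Cost grid.
#' @param seed Integer seed (fold assignment and SVM are then
#'   deterministic).
#' @return An object of class `curation_model` storing the linear
#'   weights, bias, normalization statistics and training metadata.
#' @export
train_curation_model <- function(table, labels, k = 5,
                                 costs = c(0.1, 1, 10), seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present to train the classifier.")
  }
  feats <- extract_contour_features(table)
  y <- factor(ifelse(labels, "good", "bad"), levels = c("bad", "good"))
  wts <- inverse_class_weights(y)

  cv_err <- vapply(costs, function(co) {
    cross_validate_matrix(feats$x, y, k = k, cost = co, weights = wts,
                          seed = seed)
  }, numeric(1))
  cost <- costs[which.min(cv_err)]

  fit <- with_seed(seed, e1071::svm(
    feats$x, y, kernel = "linear", cost = cost, scale = FALSE,
    class.weights = wts))
  w <- crossprod(fit$coefs, fit$SV)[1, ]
  bias <- -fit$rho
  # libsvm orients the decision value towards whichever class it saw
  # first; flip so that positive always means a good contour
  dec <- as.vector(feats$x %*% w) + bias
  if (mean((dec > 0) == (y == "good")) < 0.5) {
    w <- -w
    bias <- -bias
  }
  structure(
    list(weights = w, bias = bias, cost = cost,
         stats = feats$stats, n = nrow(feats$x), seed = seed,
         cv_error = min(cv_err), svm = fit,
         positive_is = "good"),
    class = "curation_model")
}

inverse_class_weights <- function(y) {
  counts <- vapply(levels(y), function(l) sum(y == l), numeric(1))
  w <- 1 / counts
  w / sum(w) * length(w)
}

# internal: k-fold CV error of a linear SVM on a prepared matrix
cross_validate_matrix <- function(x, y, k, cost, weights, seed) {
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  errs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE, class.weights = weights)
    mean(predict(fit, x[!tr, , drop = FALSE]) != y[!tr])
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

#' Cross-validated misclassification rate of the curation classifier
#'
#' @inheritParams train_curation_model
#' @param k Number of folds (default 10; `k = n` gives leave-one-out).
#' @param cost SVM cost parameter.
#' @return The mean misclassification rate across folds.
#' @export
cross_validate <- function(table, labels, k = 10, cost = 1, seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present.")
  feats <- extract_contour_features(table)
  y <- factor(ifelse(labels, "good", "bad"), levels = c("bad", "good"))
  wts <- inverse_class_weights(y)
  cross_validate_matrix(feats$x, y, k = min(k, nrow(feats$x)), cost = cost,
                        weights = wts, seed = seed)
}

# decision values of the stored linear rule (positive = good)
curation_scores <- function(model, table) {
  feats <- extract_contour_features(table, stats = model$stats)
  as.vector(feats$x %*% model$weights + model$bias)
}

#' Area under the ROC curve by the rank statistic
#'
#' AUROC computed as the normalized Mann-Whitney statistic with midrank
#' tie handling, which equals trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Logical, `TRUE` = positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes needed for AUROC.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate the curation classifier on labelled data
#'
#' @param model A [train_curation_model()] fit.
#' @param table Labelled cell table.
#' @param labels Logical or 0/1, `TRUE` = good contour.
#' @return One-row tibble: confusion counts (`tp`, `fp`, `tn`, `fn`),
#'   `auroc`, `balanced_rate` (mean of sensitivity and specificity) and
#'   `misclassification`.
#' @export
evaluate_classifier <- function(model, table, labels) {
  classifier_report(curation_scores(model, table), labels)
}

#' Performance report from decision values and labels
#'
#' @param scores Numeric decision values; `> 0` predicts positive.
#' @param labels Logical or 0/1 true labels.
#' @return One-row tibble as in [evaluate_classifier()].
#' @export
classifier_report <- function(scores, labels) {
  labels <- as.logical(labels)
  pred <- scores > 0
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    auroc = auroc(scores, labels),
    balanced_rate = (sens + spec) / 2,
    misclassification = (fp + fn) / length(labels)
  )
}

#' Apply a curation model to filter a cell table
#'
#' @param model A `curation_model`.
#' @param table Cell table to filter.
#' @return A list: `cells` (rows classified as good) and `log` (one-row
#'   tibble with retained/rejected counts).
#' @export
apply_curation <- function(model, table) {
  keep <- curation_scores(model, table) > 0
  list(
    cells = table[keep, , drop = FALSE],
    log = tibble(n_input = nrow(table), n_retained = sum(keep),
                 n_rejected = sum(!keep))
  )
}

#' @export
print.curation_model <- function(x, ...) {
  cat(sprintf(
    "<curation_model> linear SVM, cost %.3g, trained on %d cells (cv error %.3f)\n",
    x$cost, x$n, x$cv_error))
  invisible(x)
}

#' @rdname train_curation_model
#' @param x A `curation_model`.
#' @param ... Unused.
#' @method tidy curation_model
#' @export
tidy.curation_model <- function(x, ...) {
  tibble(term = c(names(x$weights), "(bias)"),
         estimate = c(unname(x$weights), x$bias))
}

#' Serialize / restore a curation model as JSON
#'
#' Stores the linear weights, bias, normalization statistics and training
#' metadata; the restored model reproduces decisions exactly (the rule is
#' a deterministic function of the stored weights).
#'
#' @param model A `curation_model`.
#' @param path File path.
#' @return `write_curation_model()` returns `path` invisibly;
#'   `read_curation_model()` returns a `curation_model`.
#' @export
write_curation_model <- function(model, path) {
  obj <- list(
    weights = as.list(model$weights), bias = model$bias, cost = model$cost,
    stats = model$stats, n = model$n, seed = model$seed,
    cv_error = model$cv_error)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curation_model
#' @export
read_curation_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = unlist(obj$weights), bias = obj$bias, cost = obj$cost,
         stats = as_tibble(obj$stats), n = obj$n, seed = obj$seed,
         cv_error = obj$cv_error, svm = NULL, positive_is = "good"),
    class = "curation_model")
}
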