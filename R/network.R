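# Feature-level relevance network: collinearity screening, binned mutual
# information, data-processing-inequality pruning, bootstrap support.

#' Belsley collinearity diagnostics
#'
#' Columns are scaled to unit norm and singular-value decomposed;
#' condition indices are `sigma_max / sigma_i`. Features whose
#' variance-decomposition proportion exceeds `vdp_threshold` on any index
#' above `threshold` are implicated in a near-degeneracy and flagged for
#' exclusion.
#'
#' @param x Numeric matrix or tibble of features (columns) by
#'   observations (rows); a `strain_id` column is ignored.
#' @param threshold Classical condition-index threshold (default 30).
#' @param vdp_threshold Variance-decomposition proportion above which a
#'   feature counts as implicated (default 0.5).
#' @return A list: `retained` / `excluded` feature names,
#'   `condition_indices`, and the `vdp` matrix (indices x features).
#' @export
belsley_screen <- function(x, threshold = 30, vdp_threshold = 0.5) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "strain_id"), drop = FALSE])
  }
  if (anyNA(x)) abort("collinearity screening requires complete data.")
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0)) abort("zero-norm column(s) present.")
  xs <- sweep(x, 2, norms, "/")
  sv <- svd(xs)
  d <- sv$d
  d[d < .Machine$double.eps * max(d)] <- .Machine$double.eps * max(d)
  idx <- max(d) / d

  # variance-decomposition proportions: phi_ji over indices i for each
  # coefficient j, normalised per feature
  phi <- sweep(sv$v^2, 2, d^2, "/") # features x indices, v_ji^2 / d_i^2
  vdp <- t(sweep(phi, 1, rowSums(phi), "/")) # indices x features
  colnames(vdp) <- colnames(x)

  bad_idx <- which(idx > threshold)
  implicated <- if (length(bad_idx)) {
    colnames(x)[apply(vdp[bad_idx, , drop = FALSE] > vdp_threshold, 2, any)]
  } else {
    character(0)
  }
  list(retained = setdiff(colnames(x), implicated),
       excluded = implicated,
       condition_indices = idx,
       vdp = vdp)
}

#' Mutual information between two continuous variables
#'
#' Rank-transforms both variables (making the estimate invariant to
#' monotone rescaling), bins each into `n_bins` equal-frequency bins
#' (default the cube-root rule `ceiling(n^(1/3))`), and computes plug-in
#' mutual information with the Miller-Madow bias correction; the result
#' is clamped at zero.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of bins per margin, or `NULL` for the cube-root
#'   rule.
#' @return Mutual information in nats.
#' @examples
#' x <- rnorm(1e4); mutual_information(x, x + rnorm(1e4)) # > 0
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8) abort("too few complete observations.")
  b <- n_bins %||% ceiling(n^(1 / 3))
  bx <- equal_freq_bin(x, b)
  by <- equal_freq_bin(y, b)
  joint <- tabulate(bx + (by - 1L) * b, nbins = b * b) / n
  px <- tabulate(bx, nbins = b) / n
  py <- tabulate(by, nbins = b) / n
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- ent(px) + ent(py) - ent(joint)
  mm <- (sum(px > 0) + sum(py > 0) - sum(joint > 0) - 1) / (2 * n)
  max(mi + mm, 0)
}

equal_freq_bin <- function(x, b) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / length(x) * b))
}

#' Mutual-information matrix of a feature table
#'
#' @param x Numeric matrix / tibble (observations x features); a
#'   `strain_id` column is ignored.
#' @param n_bins Passed to [mutual_information()].
#' @return Symmetric MI matrix in nats, zero diagonal.
#' @export
mi_matrix <- function(x, n_bins = NULL) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "strain_id"), drop = FALSE])
  }
  p <- ncol(x)
  m <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      m[i, j] <- m[j, i] <- mutual_information(x[, i], x[, j],
                                               n_bins = n_bins)
    }
  }
  m
}

#' ARACNE pruning by the data-processing inequality
#'
#' For every triple of features, the weakest edge is removed when it is
#' strictly weaker than both others (optionally relaxed by
#' `dpi_tolerance`): `(i, j)` is dropped if
#' `MI_ij < min(MI_ik, MI_jk) * (1 - dpi_tolerance)` for some `k`. All
#' removals are evaluated against the original MI matrix, so the result
#' is order-independent, idempotent, and ties are kept (conservative).
#'
#' @param mi Symmetric MI matrix.
#' @param dpi_tolerance Tolerance in \[0, 1\); 0 = strict.
#' @param mi_threshold Edges with MI at or below this value are removed
#'   before the DPI pass.
#' @return Logical adjacency matrix of retained edges.
#' @export
aracne <- function(mi, dpi_tolerance = 0, mi_threshold = 0) {
  p <- nrow(mi)
  adj <- mi > mi_threshold
  diag(adj) <- FALSE
  keep <- adj
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (!adj[i, j]) next
      for (k in seq_len(p)) {
        if (k == i || k == j || !adj[i, k] || !adj[j, k]) next
        if (mi[i, j] < min(mi[i, k], mi[j, k]) * (1 - dpi_tolerance)) {
          keep[i, j] <- keep[j, i] <- FALSE
          break
        }
      }
    }
  }
  keep
}

#' Null-significance threshold for binned mutual information
#'
#' Under independence, `2 * n * MI_plugin` is asymptotically
#' chi-squared with `(b - 1)^2` degrees of freedom; this returns the
#' corresponding upper-alpha quantile of the Miller-Madow-corrected
#' estimate (full bin occupancy assumed). Edges below it are
#' indistinguishable from noise and are dropped before the DPI pass.
#'
#' @param n Sample size.
#' @param b Bins per margin (default the cube-root rule).
#' @param alpha Upper-tail probability (default 0.05).
#' @return Threshold in nats.
#' @export
mi_null_threshold <- function(n, b = ceiling(n^(1 / 3)), alpha = 0.05) {
  df <- (b - 1)^2
  (stats::qchisq(1 - alpha, df) - df) / (2 * n)
}

#' Bootstrap a mutual-information relevance network
#'
#' Resamples observations with replacement `n_boot` times, recomputes the
#' full MI matrix and ARACNE pruning on each replicate, and retains the
#' edges present in more than `support_threshold` of the replicate
#' networks. Within each replicate, edges whose MI is indistinguishable
#' from the independence null are discarded before the DPI pass, so
#' features carrying no information never accumulate support. Because
#' resampling duplicates rows (which inflates binned MI), the default
#' null threshold is calibrated by permutation on bootstrap-resampled
#' independent pairs rather than by the iid chi-square approximation of
#' [mi_null_threshold()].
#'
#' @param x Feature table (observations x features); `strain_id` column
#'   ignored.
#' @param n_boot Bootstrap replicates (the reference analysis used 200).
#' @param support_threshold Minimum containment fraction (default 0.7).
#' @param dpi_tolerance,n_bins Passed through.
#' @param mi_threshold Minimum MI for an edge to enter a replicate
#'   network; `NULL` (default) calibrates it as described above.
#' @param seed Integer seed; support values are seed-deterministic.
#' @return An object of class `pheno_network`: tibble `edges`
#'   (`feature_a`, `feature_b`, `mi_nats`, `support`, `retained`), the
#'   point-estimate MI matrix `mi`, and the parameters.
#' @export
bootstrap_network <- function(x, n_boot = 200, support_threshold = 0.7,
                              dpi_tolerance = 0, n_bins = NULL,
                              mi_threshold = NULL, seed = 1) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "strain_id"), drop = FALSE])
  }
  if (anyNA(x)) abort("network inference requires complete data.")
  p <- ncol(x)
  counts <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  with_seed(seed, {
    if (is.null(mi_threshold)) {
      # resampling duplicates rows, which inflates binned MI above the
      # iid chi-square null; calibrate the edge threshold by permutation
      # on bootstrap-resampled independent pairs instead
      n <- nrow(x)
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      null_mi <- vapply(seq_len(60), function(i) {
        idx <- sample.int(n, replace = TRUE)
        mutual_information(z1[idx], z2[idx], n_bins = n_bins)
      }, numeric(1))
      mi_threshold <- stats::quantile(null_mi, 0.95, names = FALSE)
    }
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(x), replace = TRUE)
      mib <- mi_matrix(x[idx, , drop = FALSE], n_bins = n_bins)
      counts <- counts + aracne(mib, dpi_tolerance = dpi_tolerance,
                                mi_threshold = mi_threshold)
    }
  })
  support <- counts / n_boot
  mi0 <- mi_matrix(x, n_bins = n_bins)

  ut <- which(upper.tri(support), arr.ind = TRUE)
  edges <- tibble(
    feature_a = colnames(x)[ut[, 1]],
    feature_b = colnames(x)[ut[, 2]],
    mi_nats = mi0[ut],
    support = support[ut]
  ) |>
    mutate(retained = .data$support > support_threshold) |>
    arrange(dplyr::desc(.data$support), dplyr::desc(.data$mi_nats))

  structure(
    list(edges = edges, mi = mi0, support = support,
         n_boot = n_boot, support_threshold = support_threshold,
         dpi_tolerance = dpi_tolerance),
    class = "pheno_network")
}

#' @export
print.pheno_network <- function(x, ...) {
  cat(sprintf(
    "<pheno_network> %d features, %d edges retained (support > %.0f%%, %d bootstraps)\n",
    nrow(x$mi), sum(x$edges$retained), 100 * x$support_threshold, x$n_boot))
  invisible(x)
}

#' @rdname bootstrap_network
#' @param x,object A `pheno_network`.
#' @param ... Unused.
#' @method tidy pheno_network
#' @export
tidy.pheno_network <- function(x, ...) filter(x$edges, .data$retained)

#' @rdname bootstrap_network
#' @method glance pheno_network
#' @export
glance.pheno_network <- function(x, ...) {
  tibble(n_features = nrow(x$mi), n_edges = sum(x$edges$retained),
         n_boot = x$n_boot, support_threshold = x$support_threshold)
}

#' @rdname bootstrap_network
#' @method autoplot pheno_network
#' @export
autoplot.pheno_network <- function(object, ...) {
  g <- pheno_network_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  el <- igraph::as_data_frame(g)
  el <- left_join(el, rename(nodes, xa = "x", ya = "y"),
                  by = c(from = "name"))
  el <- left_join(el, rename(nodes, xb = "x", yb = "y"),
                  by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = el,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$support),
      colour = "grey50") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), limits = c(0, 1)) +
    ggplot2::theme_void()
}

pheno_network_igraph <- function(network) {
  edges <- filter(network$edges, .data$retained)
  igraph::graph_from_data_frame(
    select(edges, "feature_a", "feature_b", "mi_nats", "support"),
    directed = FALSE,
    vertices = rownames(network$mi))
}

#' Write a phenotype network to GraphML / CSV
#'
#' @param network A `pheno_network`.
#' @param path Output file; `.graphml` or `.csv` by extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(pheno_network_igraph(network), path,
                        format = "graphml")
  } else {
    readr::write_csv(filter(network$edges, .data$retained), path)
  }
  invisible(path)
}
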