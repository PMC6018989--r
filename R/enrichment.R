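# Categorical (COG/GO-style) and spatial (SAFE-style) enrichment.

#' Two-tailed hypergeometric term enrichment
#'
#' For every annotation term, tests whether the member set contains more
#' (or fewer) annotated strains than expected by drawing `n` strains from
#' the universe: two-tailed
#' `p = min(1, 2 * min(P[X <= k], P[X >= k]))` under
#' Hypergeometric(N, K, n). P-values are adjusted by Benjamini-Hochberg
#' (appropriate for largely independent vocabularies such as COG
#' categories) or Benjamini-Yekutieli (dependence-robust, used for GO).
#'
#' @param member_set Strain/gene ids in the set of interest (must be a
#'   subset of `universe`).
#' @param universe All ids eligible for membership.
#' @param annotations Tibble with columns `id`, `term` (one row per
#'   id-term pair); terms with no annotated id in the universe are
#'   dropped.
#' @param adjust `"BH"` or `"BY"`.
#' @return Tibble: `term`, `k` (annotated in set), `K` (annotated in
#'   universe), `n` (set size), `N` (universe size), `p`, `q`,
#'   `direction` (`"enriched"`/`"depleted"`).
#' @export
term_enrichment <- function(member_set, universe, annotations,
                            adjust = c("BH", "BY")) {
  adjust <- match.arg(adjust)
  check_columns(annotations, c("id", "term"), "annotation map")
  offenders <- setdiff(member_set, universe)
  if (length(offenders)) {
    abort(paste("member ids not in the universe:",
                paste(head(offenders, 5), collapse = ", ")))
  }
  ann <- filter(annotations, .data$id %in% universe)
  N <- length(unique(universe))
  n <- length(unique(member_set))
  rows <- ann |>
    group_by(.data$term) |>
    summarise(K = dplyr::n_distinct(.data$id),
              k = dplyr::n_distinct(intersect(.data$id, member_set)),
              .groups = "drop") |>
    filter(.data$K > 0)
  if (nrow(rows) == 0) {
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  q = numeric(), direction = character()))
  }
  p <- map_dbl(seq_len(nrow(rows)), function(i) {
    hyper_two_tailed(rows$k[i], rows$K[i], n, N)
  })
  expected <- rows$K * n / N
  tibble(
    term = rows$term, k = rows$k, K = rows$K, n = n, N = N,
    p = p, q = fdr_adjust(p, method = adjust),
    direction = ifelse(rows$k >= expected, "enriched", "depleted")
  ) |>
    arrange(.data$p)
}

# two-tailed hypergeometric by tail doubling, capped at 1
hyper_two_tailed <- function(k, K, n, N) {
  lower <- phyper(k, K, N - K, n)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' False-discovery-rate adjustment
#'
#' Step-up FDR control: Benjamini-Hochberg for independent (or positively
#' dependent) tests, Benjamini-Yekutieli with the harmonic-sum penalty
#' `c(m) = sum(1/i)` for arbitrary dependence.
#'
#' @param pvals Numeric p-values.
#' @param method `"BH"` or `"BY"`.
#' @return Adjusted q-values, same length.
#' @export
fdr_adjust <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  p.adjust(pvals, method = method)
}

#' Spatial enrichment on an embedding (SAFE-style)
#'
#' Treats a 2D embedding as a similarity map and asks, for each point and
#' each binary attribute, whether the attribute is locally
#' over-represented: the neighbourhood is the disc of radius equal to the
#' `radius_percentile` percentile of all pairwise distances, and the
#' annotated count within it is tested against the hypergeometric null
#' given the neighbourhood size and the attribute's global frequency.
#' Benjamini-Yekutieli adjustment is applied across all point-by-term
#' tests. Alongside the analytic test, a permutation background (mean and
#' sd of the local count over `n_perm` attribute permutations, and an
#' empirical p) is reported, mirroring the permutation formulation of the
#' original spatial-enrichment method.
#'
#' @param embedding n x 2 coordinate matrix with row names, or a tibble
#'   with `strain_id`, `x`, `y`.
#' @param attributes Binary matrix (strains x terms) with row and column
#'   names, or tibble with `strain_id` plus 0/1 term columns.
#' @param radius_percentile Percentile (0-100) of the pairwise-distance
#'   distribution defining the neighbourhood radius (default 1).
#' @param n_perm Attribute permutations for the empirical background.
#' @param alpha Significance level applied to the BY-adjusted q-values.
#' @param seed Integer seed for the permutations.
#' @return A list: `nodes` (tibble `strain_id`, `term`, `k_local`,
#'   `n_local`, `p`, `q`, `significant`, `perm_mean`, `perm_sd`,
#'   `p_perm`), `radius`, and `regions` (per term, the ids of significant
#'   points).
#' @export
safe_enrichment <- function(embedding, attributes, radius_percentile = 1,
                            n_perm = 1000, alpha = 0.05, seed = 1) {
  emb <- if (is.matrix(embedding)) {
    embedding
  } else {
    check_columns(embedding, c("strain_id", "x", "y"), "embedding")
    m <- as.matrix(embedding[, c("x", "y")])
    rownames(m) <- embedding$strain_id
    m
  }
  n <- nrow(emb)
  if (n < 20) abort("need at least 20 points for spatial enrichment.")

  att <- if (is.matrix(attributes)) {
    attributes
  } else {
    check_columns(attributes, "strain_id", "attributes")
    m <- as.matrix(attributes[, setdiff(names(attributes), "strain_id")])
    rownames(m) <- attributes$strain_id
    m
  }
  att <- att[rownames(emb), , drop = FALSE]
  keep <- colSums(att) > 0
  if (!all(keep)) {
    warn(paste("skipping all-zero attribute column(s):",
               paste(colnames(att)[!keep], collapse = ", ")))
    att <- att[, keep, drop = FALSE]
  }
  if (ncol(att) == 0) abort("no usable attribute columns.")

  d <- as.matrix(dist(emb))
  radius <- stats::quantile(d[upper.tri(d)], radius_percentile / 100,
                            names = FALSE)
  nb <- d <= radius # disc includes the point itself

  n_local <- rowSums(nb)
  k_local <- nb %*% att # points x terms local annotated counts
  K_global <- colSums(att)

  perm_stats <- with_seed(seed, {
    sums <- array(0, dim = dim(k_local))
    sq <- array(0, dim = dim(k_local))
    ge <- array(0, dim = dim(k_local))
    for (b in seq_len(n_perm)) {
      kp <- nb %*% att[sample.int(n), , drop = FALSE]
      sums <- sums + kp
      sq <- sq + kp^2
      ge <- ge + (kp >= k_local)
    }
    list(mean = sums / n_perm,
         sd = sqrt(pmax(sq / n_perm - (sums / n_perm)^2, 0)),
         p = (ge + 1) / (n_perm + 1))
  })

  rows <- list()
  for (j in seq_len(ncol(att))) {
    p <- phyper(k_local[, j] - 1, K_global[j], n - K_global[j], n_local,
                lower.tail = FALSE)
    rows[[j]] <- tibble(
      strain_id = rownames(emb), term = colnames(att)[j],
      k_local = as.vector(k_local[, j]), n_local = n_local,
      p = p, perm_mean = perm_stats$mean[, j], perm_sd = perm_stats$sd[, j],
      p_perm = perm_stats$p[, j])
  }
  nodes <- list_rbind(rows)
  nodes$q <- fdr_adjust(nodes$p, "BY")
  nodes$significant <- nodes$q <= alpha

  regions <- nodes |>
    filter(.data$significant) |>
    group_by(.data$term) |>
    summarise(ids = list(.data$strain_id), .groups = "drop")

  list(nodes = nodes, radius = radius, regions = regions)
}
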