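# Hypergeometric term enrichment, FDR adjustment, spatial enrichment.

# brute-force two-tailed hypergeometric by full enumeration over k
hyper_oracle <- function(k, K, n, N) {
  all_k <- 0:min(K, n)
  pmf <- choose(K, all_k) * choose(N - K, n - all_k) / choose(N, n)
  lower <- sum(pmf[all_k <= k])
  upper <- sum(pmf[all_k >= k])
  min(1, 2 * min(lower, upper))
}

test_that("two-tailed hypergeometric matches exact enumeration", {
  # worked example: N = 20, K = 5, n = 5, k = 4
  p_up <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(p_up, 76 / 15504)
  ann <- tibble::tibble(id = sprintf("g%02d", 1:20),
                        term = rep(c("T", "other"), c(5, 15)))
  universe <- ann$id
  member <- c(sprintf("g%02d", 1:4), "g20") # 4 of 5 annotated
  res <- term_enrichment(member, universe, ann, adjust = "BH")
  expect_equal(res$p[res$term == "T"], 2 * p_up)
  expect_equal(res$direction[res$term == "T"], "enriched")

  # random instances vs the enumeration oracle
  set.seed(61)
  for (i in 1:30) {
    N <- sample(8:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phenoscreen:::hyper_two_tailed(k, K, n, N),
                 hyper_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("degenerate enrichment inputs behave as documented", {
  ann <- tibble::tibble(id = letters[1:10], term = rep(c("T1", "T2"), 5))
  # member set = universe -> capped p = 1 for every term
  res <- term_enrichment(letters[1:10], letters[1:10], ann)
  expect_true(all(res$p == 1))
  # terms with no annotated member in the universe are excluded
  ann2 <- rbind(ann, tibble::tibble(id = "zz", term = "T3"))
  res2 <- term_enrichment(letters[1:3], letters[1:10], ann2)
  expect_false("T3" %in% res2$term)
  # members outside the universe are an error naming offenders
  expect_error(term_enrichment(c("a", "nope"), letters[1:10], ann), "nope")
})

test_that("BH and BY match the hand-computed step-up formulas", {
  expect_equal(fdr_adjust(0.03, "BH"), 0.03)
  expect_equal(fdr_adjust(0.03, "BY"), 0.03) # c(1) = 1
  expect_equal(fdr_adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  expect_equal(fdr_adjust(c(0.01, 0.04), "BY"), c(0.03, 0.06)) # c(2) = 1.5

  # oracle re-implementation of the step-up rules on random p-vectors
  step_up <- function(p, cm) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * cm * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(62)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_adjust(p, "BH"), step_up(p, 1), tolerance = 1e-12)
    expect_equal(fdr_adjust(p, "BY"), step_up(p, sum(1 / seq_along(p))),
                 tolerance = 1e-12)
    # monotone under the step-up enforcement
    q <- fdr_adjust(p, "BH")
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

# planted spatial fixture: one tight annotated island in a diffuse cloud
safe_fixture <- function(seed = 63, n_cloud = 150, n_island = 10) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(2 * n_cloud, 0, 3), ncol = 2),
               matrix(rnorm(2 * n_island, 12, 0.25), ncol = 2))
  rownames(pts) <- sprintf("s%03d", seq_len(n_cloud + n_island))
  att <- cbind(X = c(rep(0, n_cloud), rep(1, n_island)),
               flat = rep(1, n_cloud + n_island))
  rownames(att) <- rownames(pts)
  list(pts = pts, att = att, island_ids = rownames(pts)[-(1:n_cloud)])
}

test_that("spatial enrichment finds the planted annotated island", {
  fx <- safe_fixture()
  res <- safe_enrichment(fx$pts, fx$att, n_perm = 50, seed = 1)
  # the uniformly-1 attribute is never significant
  expect_false(any(res$nodes$significant[res$nodes$term == "flat"]))
  # island nodes significant for the planted term after BY
  hits <- res$nodes$strain_id[res$nodes$term == "X" & res$nodes$significant]
  expect_true(all(fx$island_ids %in% hits))
  expect_false(any(setdiff(rownames(fx$pts), fx$island_ids) %in% hits))
  # and the permutation background agrees qualitatively
  isl <- res$nodes$term == "X" & res$nodes$strain_id %in% fx$island_ids
  expect_true(all(res$nodes$p_perm[isl] < 0.1))
})

test_that("spatial enrichment is rigid-motion invariant", {
  fx <- safe_fixture(64)
  th <- 0.7
  rot <- fx$pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- rot + 5
  rownames(rot) <- rownames(fx$pts)
  r1 <- safe_enrichment(fx$pts, fx$att, n_perm = 10, seed = 2)
  r2 <- safe_enrichment(rot, fx$att, n_perm = 10, seed = 2)
  expect_equal(r1$nodes$p, r2$nodes$p, tolerance = 1e-9)
})

test_that("spatial enrichment is calibrated under the permutation null", {
  set.seed(65)
  calls <- vapply(1:40, function(i) {
    pts <- matrix(rnorm(120), ncol = 2)
    rownames(pts) <- sprintf("s%02d", 1:60)
    att <- cbind(A = sample(rep(c(0, 1), c(45, 15))),
                 B = sample(rep(c(0, 1), c(50, 10))))
    rownames(att) <- rownames(pts)
    res <- safe_enrichment(pts, att, n_perm = 10, seed = i, alpha = 0.05)
    mean(res$nodes$significant)
  }, numeric(1))
  expect_lte(mean(calls), 0.05)
})
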