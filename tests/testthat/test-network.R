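# Collinearity screening, mutual information, ARACNE, bootstrap support.

test_that("Belsley screening flags exact and near collinearity", {
  # orthonormal columns: all indices 1, nothing excluded
  q <- qr.Q(qr(matrix(rnorm(200), ncol = 4)))
  colnames(q) <- paste0("f", 1:4)
  b <- belsley_screen(q)
  expect_equal(unname(b$condition_indices), rep(1, 4), tolerance = 1e-9)
  expect_length(b$excluded, 0)

  # duplicated column: rank deficiency implicates both copies
  x <- cbind(a = rnorm(100), b = rnorm(100))
  x <- cbind(x, c = x[, "a"])
  b2 <- belsley_screen(x)
  expect_true(all(c("a", "c") %in% b2$excluded))

  # x3 = x1 + x2 + tiny noise: condition index above 30, verified vs a
  # direct SVD oracle
  set.seed(71)
  x1 <- rnorm(500); x2 <- rnorm(500)
  x3 <- x1 + x2 + rnorm(500, 0, 1e-4)
  m <- cbind(x1 = x1, x2 = x2, x3 = x3)
  b3 <- belsley_screen(m)
  sv <- svd(sweep(m, 2, sqrt(colSums(m^2)), "/"))$d
  expect_equal(max(b3$condition_indices), max(sv) / min(sv), tolerance = 1e-9)
  expect_gt(max(b3$condition_indices), 30)
  expect_true(all(c("x1", "x2", "x3") %in% b3$excluded))
})

test_that("mutual information matches the Gaussian closed form", {
  set.seed(72)
  n <- 1e5
  for (rho in c(0.3, 0.8)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(mutual_information(x, y) + 0.5 * log(1 - rho^2)), 0.03)
  }
  # independence: MI near zero
  expect_lt(mutual_information(rnorm(1e4), rnorm(1e4)), 0.02)
  # determinism bound: y = x saturates at ln(B)
  x <- rnorm(1e4)
  b <- ceiling(1e4^(1 / 3))
  expect_equal(mutual_information(x, x), log(b), tolerance = 0.01)
  # rank invariance to monotone rescaling
  y <- 0.5 * x + rnorm(1e4, 0, 0.5)
  expect_equal(mutual_information(x, y), mutual_information(exp(x), y^3 + y),
               tolerance = 1e-12)
})

test_that("the DPI removes exactly the indirect edge of a Markov chain", {
  # closed-form Gaussian MIs for the chain X - Y - Z with rho = 0.8
  mi_g <- function(r) -0.5 * log(1 - r^2)
  mi <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  mi["X", "Y"] <- mi["Y", "X"] <- mi_g(0.8)
  mi["Y", "Z"] <- mi["Z", "Y"] <- mi_g(0.8)
  mi["X", "Z"] <- mi["Z", "X"] <- mi_g(0.64)
  adj <- aracne(mi)
  expect_true(adj["X", "Y"] && adj["Y", "Z"])
  expect_false(adj["X", "Z"])

  # tie rule: all MIs equal -> nothing removed
  tie <- matrix(0.5, 3, 3); diag(tie) <- 0
  expect_true(all(aracne(tie)[upper.tri(tie)]))

  # no triangle -> no removal
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 0.5
  two[3, 4] <- two[4, 3] <- 0.4
  expect_equal(sum(aracne(two)), 4) # both edges, symmetric

  # idempotence and subset property
  set.seed(73)
  r <- matrix(runif(36), 6); r <- (r + t(r)) / 2; diag(r) <- 0
  a1 <- aracne(r)
  a2 <- aracne(r * a1) # re-apply on the pruned graph
  expect_true(all(a1 == (a1 & (r > 0))))
  expect_equal(a2, a1 & a2) # never adds edges back
})

test_that("ARACNE recovers tree skeletons from Gaussian data", {
  # chain tree over 10 nodes, rho 0.7 per edge, n = 5000
  f1 <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 5000; p <- 10
    x <- matrix(0, n, p)
    x[, 1] <- rnorm(n)
    for (j in 2:p) x[, j] <- 0.7 * x[, j - 1] + sqrt(1 - 0.49) * rnorm(n)
    colnames(x) <- paste0("f", 1:p)
    adj <- aracne(mi_matrix(x))
    true_edges <- cbind(1:(p - 1), 2:p)
    pred <- which(adj & upper.tri(adj), arr.ind = TRUE)
    tp <- sum(apply(pred, 1, function(e) any(
      true_edges[, 1] == e[1] & true_edges[, 2] == e[2])))
    prec <- tp / nrow(pred); rec <- tp / nrow(true_edges)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(median(f1), 0.9)
})

test_that("bootstrap support separates real from spurious edges", {
  set.seed(74)
  n <- 400
  # noiseless functional chain: supports 1.0 on the chain edges
  x <- rnorm(n)
  chain <- cbind(a = x, b = 2 * x, c = -3 * x)
  net <- bootstrap_network(chain, n_boot = 20, seed = 1)
  expect_true(all(net$edges$support == 1))

  # independent columns: nothing retained at 0.7 over several seeds
  for (s in 1:5) {
    ind <- matrix(rnorm(n * 4), ncol = 4,
                  dimnames = list(NULL, letters[1:4]))
    net0 <- bootstrap_network(ind, n_boot = 30, seed = s)
    expect_equal(sum(net0$edges$retained), 0)
  }

  # n_boot = 1: supports are 0 or 1; seed determinism
  net1 <- bootstrap_network(chain, n_boot = 1, seed = 2)
  expect_true(all(net1$edges$support %in% c(0, 1)))
  net2 <- bootstrap_network(chain, n_boot = 5, seed = 3)
  net3 <- bootstrap_network(chain, n_boot = 5, seed = 3)
  expect_identical(net2$edges, net3$edges)
  expect_s3_class(tidy(net2), "tbl_df")
})

test_that("networks serialize to graphml and csv", {
  set.seed(75)
  x <- rnorm(300)
  chain <- cbind(a = x, b = x + rnorm(300, 0, 0.2), c = rnorm(300))
  net <- bootstrap_network(chain, n_boot = 10, seed = 4)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, csv)
  expect_true(file.exists(csv))
})
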