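# Exact-gradient t-distributed stochastic neighbor embedding.
#
# Screens of a few hundred to a few thousand strains are small enough for
# the exact O(n^2) gradient; no tree approximation is needed. The
# implementation follows the reference algorithm: per-point bandwidths
# calibrated to a target perplexity by bisection, symmetrized input
# affinities, Student-t low-dimensional kernel, gradient descent with
# momentum and an early-exaggeration phase.

# per-row conditional affinities at the requested perplexity
tsne_input_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { # beta too large
        hi <- beta; beta <- beta / 2; next
      }
      pj <- w / sw
      h <- -sum(pj[pj > 0] * log(pj[pj > 0])) # Shannon entropy
      if (abs(h - target) < 1e-5) break
      if (h > target) { # too flat: raise beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' 2D t-SNE embedding (exact gradient)
#'
#' @param x Numeric matrix (observations x variables), no missing values.
#' @param perplexity Target perplexity; clamped to `(n - 1) / 3` when the
#'   dataset is small.
#' @param n_iter Gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @param exaggeration Early-exaggeration factor applied for the first
#'   quarter of the iterations.
#' @return n x 2 coordinate matrix.
#' @export
embed_tsne <- function(x, perplexity = 30, n_iter = 400, seed = 1,
                       exaggeration = 12) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("t-SNE input must not contain missing values.")
  n <- nrow(x)
  if (n < 10) abort("need at least 10 observations to embed.")
  perplexity <- min(perplexity, (n - 1) / 3)

  d2 <- as.matrix(dist(x))^2
  p <- tsne_input_affinities(d2, perplexity)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    eta <- max(50, n / exaggeration)
    stop_exagg <- floor(n_iter / 4)
    momentum <- 0.5
    for (iter in seq_len(n_iter)) {
      pp <- if (iter <= stop_exagg) p * exaggeration else p
      sum_y <- rowSums(y^2)
      num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(y))
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      stiff <- 4 * (pp - q) * num
      grad <- (diag(rowSums(stiff)) - stiff) %*% y
      gains <- pmax(0.01,
                    ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
      inc <- momentum * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
      if (iter == 250) momentum <- 0.8
    }
    y
  })
}
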