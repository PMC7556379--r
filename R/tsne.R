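# Exact (O(n^2)) t-distributed stochastic neighbor embedding.
# Standard formulation: Gaussian input affinities with per-point bandwidths
# found by bisection to match a target perplexity, symmetrized and
# exaggerated early; Student-t low-dimensional affinities; gradient descent
# with momentum and adaptive gains. Deterministic under `seed`.

.tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw   # Shannon entropy (nats)
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    pi <- w / max(sum(w), .Machine$double.xmin)
    p[i, -i] <- pi
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

.tsne <- function(x, perplexity = 30, seed = 1L, max_iter = 500L, eta = 200,
                  exaggeration = 12, exag_iter = 100L) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  p <- .tsne_affinities(x, perplexity)
  y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  up <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= exag_iter) exaggeration else 1
    d2y <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + d2y)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (p * ex - q) * num
    grad <- 4 * (rowSums(l) * y - l %*% y)
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(up), gains + 0.2, gains * 0.8))
    up <- mom * up - eta * gains * grad
    y <- y + up
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' Embed a cohort in 2D (t-SNE)
#'
#' Projects the 53-dimensional answer vectors to two dimensions with an exact
#' t-SNE so the cohort's diagnostic-system structure can be inspected
#' visually, e.g. whether any diagnostic group forms a separable cluster.
#'
#' @param cohort A cohort data frame with at least 5 respondents.
#' @param seed Integer seed; the embedding is deterministic under a fixed
#'   seed.
#' @param perplexity Target perplexity of the input affinities (default 30,
#'   clamped to `(n - 1) / 3` for small cohorts).
#' @param max_iter Gradient-descent iterations (default 500).
#' @return A data frame with columns `respondent_id`, `x`, `y`,
#'   `diagnostic_system`, one row per respondent in cohort order.
#' @export
embed_cohort <- function(cohort, seed = 1L, perplexity = 30, max_iter = 500L) {
  validate_cohort(cohort)
  if (nrow(cohort) < 5L) stop_data("embedding needs at least 5 respondents")
  y <- .tsne(answer_matrix(cohort), perplexity = perplexity, seed = seed,
             max_iter = max_iter)
  data.frame(respondent_id = cohort$respondent_id, x = y[, 1], y = y[, 2],
             diagnostic_system = cohort$diagnostic_system,
             stringsAsFactors = FALSE)
}
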