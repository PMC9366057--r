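# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the MVN density is evaluated via a Cholesky
# factorization of the covariance, DAG enumeration is brute force over all
# orientation assignments, and the AUC oracle loops over all
# label-discordant pairs.

# log multivariate-normal density at the rows of x, from first principles
oracle_mvn_logdens <- function(mean, sigma, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - length(mean) / 2 * log(2 * pi)
}

# all DAGs over the given nodes: every assignment of {none, ->, <-} to each
# unordered pair, filtered for acyclicity
oracle_enumerate_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- utils::combn(p, 2)
  npairs <- ncol(pairs)
  out <- list()
  for (code in seq_len(3^npairs) - 1L) {
    digs <- integer(npairs)
    c0 <- code
    for (k in seq_len(npairs)) { digs[k] <- c0 %% 3L; c0 <- c0 %/% 3L }
    arcs <- NULL
    for (k in seq_len(npairs)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (digs[k] == 1L) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
      if (digs[k] == 2L) arcs <- rbind(arcs, c(nodes[j], nodes[i]))
    }
    d <- tryCatch(new_dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(d)) out[[length(out) + 1L]] <- d
  }
  out
}

# O(n^2) pairwise AUC with ties credited one half
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small fixed two-node network: X ~ N(0,1), Y = 2X + 1 + N(0,1)
toy_xy_network <- function() {
  dag <- new_dag(c("X", "Y"), rbind(c("X", "Y")))
  new_gbn(dag, list(
    X = list(parents = character(0), beta = numeric(0), intercept = 0, sigma = 1),
    Y = list(parents = "X", beta = c(X = 2), intercept = 1, sigma = 1)))
}

# random gbn over p nodes with moderate density, reproducible
random_gbn <- function(p, seed, expected_arcs = p) {
  d <- make_random_dag(p, min(expected_arcs, p * (p - 1) / 2), seed = seed)
  make_random_network(d, seed = seed + 1000L)
}

# two vectors of length n with sample correlation exactly r (up to
# floating point), built by Gram-Schmidt on centered unit vectors
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- rnorm(n)
  e <- scale(e - x * sum(e * x) / sum(x * x))[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  cbind(x = x, y = y)
}
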