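# Group-wise Pearson correlation structure: matrices, their elementwise
# difference, and a label-permutation test of the null hypothesis that the
# two groups share one correlation matrix.

#' Pearson correlation matrix of a profile matrix
#'
#' @param data Numeric matrix, n >= 3 rows, no zero-variance column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(data) {
  x <- as.matrix(data)
  if (nrow(x) < 3) stop("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  stats::cor(x)
}

#' Elementwise difference of two correlation matrices
#'
#' @param corr_a,corr_b Conformable symmetric correlation matrices.
#' @return `corr_a - corr_b` (antisymmetric under argument swap, zero
#'   diagonal).
#' @export
correlation_difference <- function(corr_a, corr_b) {
  if (!all(dim(corr_a) == dim(corr_b))) stop("matrices are not conformable")
  corr_a - corr_b
}

# internal: test statistic on the off-diagonal correlation difference
corr_diff_stat <- function(ca, cb, statistic) {
  d <- ca - cb
  diag(d) <- 0
  if (statistic == "frobenius") sqrt(sum(d^2)) else max(abs(d))
}

#' Permutation test for equality of two correlation matrices
#'
#' Statistic: the Frobenius norm (default) or maximum absolute entry of
#' the off-diagonal correlation difference. The null distribution is built
#' by permuting group labels over the pooled rows; the p-value uses the
#' add-one convention `(1 + #{perm >= obs}) / (n_perm + 1)`, so it is
#' never exactly zero.
#'
#' @param group_a,group_b Numeric profile matrices with identical columns.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param statistic `"frobenius"` or `"maxabs"`.
#' @return Object of class `corr_comparison`: `corr_a`, `corr_b`,
#'   `difference`, `statistic`, `p_value`, `n_perm`, `stat_name`.
#' @export
permutation_equality_test <- function(group_a, group_b, n_perm = 10000,
                                      seed = 1L,
                                      statistic = c("frobenius", "maxabs")) {
  statistic <- match.arg(statistic)
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (nrow(a) < 3 || nrow(b) < 3) stop("both groups need at least 3 rows")
  ca <- pearson_matrix(a)
  cb <- pearson_matrix(b)
  obs <- corr_diff_stat(ca, cb, statistic)
  pooled <- rbind(a, b)
  na <- nrow(a); ntot <- nrow(pooled)
  exceed <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(ntot, na)
      pa <- stats::cor(pooled[ia, , drop = FALSE])
      pb <- stats::cor(pooled[-ia, , drop = FALSE])
      corr_diff_stat(pa, pb, statistic) >= obs
    }, logical(1)))
  })
  structure(list(corr_a = ca, corr_b = cb,
                 difference = correlation_difference(ca, cb),
                 statistic = obs,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, stat_name = statistic),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("Correlation-matrix comparison (%s statistic = %.4f)\n",
              x$stat_name, x$statistic))
  cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}
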