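# What-if conditional imputation among clinical scales: clamp chosen
# scales at observed values, condition the network's joint multivariate
# normal (Schur complement), and tabulate paired differences of the
# conditional means under the two group networks.

#' Exact conditional distribution given clamped scales
#'
#' Conditions the network's joint multivariate normal on the clamped
#' coordinates: mean `mu_f + S_fc S_cc^-1 (x_c - mu_c)`, covariance
#' `S_ff - S_fc S_cc^-1 S_cf`. Clamping every node returns a valid
#' zero-dimensional distribution.
#'
#' @param network A `gbn` (or an `mvn_joint`).
#' @param clamped Named numeric vector of clamped scale values.
#' @return An `mvn_joint` over the free scales.
#' @export
conditional_distribution <- function(network, clamped) {
  joint <- if (inherits(network, "mvn_joint")) network else to_joint_mvn(network)
  cn <- names(clamped)
  if (is.null(cn) || !all(cn %in% joint$nodes))
    stop("clamped scales must be named and be network nodes")
  free <- setdiff(joint$nodes, cn)
  if (!length(free)) {
    return(structure(list(nodes = character(0), mean = numeric(0),
                          sigma = matrix(0, 0, 0)), class = "mvn_joint"))
  }
  if (!length(cn)) return(joint)
  Scc <- joint$sigma[cn, cn, drop = FALSE]
  sol <- tryCatch(solve(Scc, cbind(clamped - joint$mean[cn])),
                  error = function(e)
                    stop("singular clamped block: cannot condition", call. = FALSE))
  Sfc <- joint$sigma[free, cn, drop = FALSE]
  mu <- joint$mean[free] + as.vector(Sfc %*% sol)
  Sig <- joint$sigma[free, free, drop = FALSE] -
    Sfc %*% solve(Scc, t(Sfc))
  Sig <- (Sig + t(Sig)) / 2
  names(mu) <- free
  dimnames(Sig) <- list(free, free)
  structure(list(nodes = free, mean = mu, sigma = Sig), class = "mvn_joint")
}

# internal: draw n rows from an mvn_joint (eigendecomposition square root,
# robust to positive-semidefinite covariances with zero directions)
rmvn <- function(n, joint) {
  p <- length(joint$nodes)
  if (p == 0) return(matrix(0, n, 0))
  e <- eigen(joint$sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  root <- e$vectors %*% (t(e$vectors) * sqrt(lam))
  z <- matrix(stats::rnorm(n * p), n, p)
  out <- sweep(z %*% root, 2, joint$mean, "+")
  colnames(out) <- joint$nodes
  out
}

#' Sample free scales given clamped scales
#'
#' Draws from the exact Gaussian conditional of [conditional_distribution()].
#'
#' @inheritParams conditional_distribution
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return `n x #free` matrix (zero columns if everything is clamped).
#' @export
clamp_and_sample <- function(network, clamped, n, seed = NULL) {
  stopifnot(n >= 1)
  cond <- conditional_distribution(network, clamped)
  run <- function() rmvn(n, cond)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' What-if difference table for a set of scales
#'
#' For each scale `s` in `scales`: draw `n` clamp values from
#' `source_net`'s marginal of `s`; for every other scale `t` in `scales`
#' compute the conditional mean of `t` given `s` under `net_a` and under
#' `net_b` at each draw (both networks see identical draws, a paired
#' design); report the mean paired difference (a minus b), its SD, and a
#' paired t-test p-value. The diagonal records the clamped draws' mean and
#' SD.
#'
#' @param net_a,net_b `gbn`s sharing the node set (conventionally healthy
#'   and schizophrenia).
#' @param source_net Network whose marginal supplies the clamp draws;
#'   defaults to `net_b` (the patient model).
#' @param scales Character vector of scales to cross-impute.
#' @param n Draws per clamped scale.
#' @param seed Integer seed.
#' @param impute `"mean"` (conditional means; default) or `"draw"`
#'   (single stochastic imputations, noisier).
#' @return Object of class `whatif_table`: `scales`, `mean_diff`, `sd_diff`,
#'   `p_value` (square matrices, diagonal = clamp mean / clamp sd / NA),
#'   `n`, `impute`.
#' @export
whatif_difference_table <- function(net_a, net_b, source_net = net_b,
                                    scales = c("D", "Pt", "Sc"), n = 1000,
                                    seed = 1L, impute = c("mean", "draw")) {
  impute <- match.arg(impute)
  stopifnot(all(scales %in% net_a$dag$nodes), all(scales %in% net_b$dag$nodes))
  ja <- to_joint_mvn(net_a)
  jb <- to_joint_mvn(net_b)
  js <- to_joint_mvn(source_net)
  k <- length(scales)
  mean_diff <- sd_diff <- p_value <- matrix(NA_real_, k, k,
                                            dimnames = list(scales, scales))
  withr::with_seed(as.integer(seed), {
    for (s in scales) {
      draws <- stats::rnorm(n, js$mean[s], sqrt(js$sigma[s, s]))
      mean_diff[s, s] <- mean(draws)
      sd_diff[s, s] <- stats::sd(draws)
      for (t_ in setdiff(scales, s)) {
        imp <- function(j) {
          slope <- j$sigma[t_, s] / j$sigma[s, s]
          mu <- j$mean[t_] + slope * (draws - j$mean[s])
          if (impute == "draw") {
            resid_var <- j$sigma[t_, t_] - slope * j$sigma[t_, s]
            mu <- mu + stats::rnorm(n, 0, sqrt(max(resid_var, 0)))
          }
          mu
        }
        d <- imp(ja) - imp(jb)
        mean_diff[s, t_] <- mean(d)
        sd_diff[s, t_] <- stats::sd(d)
        p_value[s, t_] <- if (stats::sd(d) == 0) {
          if (mean(d) == 0) 1 else 0  # identical networks vs constant offset
        } else stats::t.test(d)$p.value
      }
    }
  })
  structure(list(scales = scales, mean_diff = mean_diff, sd_diff = sd_diff,
                 p_value = p_value, n = n, impute = impute),
            class = "whatif_table")
}

#' @export
print.whatif_table <- function(x, ...) {
  cat("What-if paired differences (rows = clamped scale; diagonal = clamp",
      "mean (SD))\n")
  k <- length(x$scales)
  cells <- matrix("", k, k, dimnames = list(x$scales, x$scales))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cells[i, j] <- sprintf("%.2f (%.2f)", x$mean_diff[i, j], x$sd_diff[i, j])
  }
  print(as.data.frame(cells))
  invisible(x)
}
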