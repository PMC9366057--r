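# Linear-Gaussian Bayesian networks: maximum-likelihood fitting, density
# evaluation, decomposable BIC scoring and arc strength.
#
# Every per-node model is child = c + beta' parents + N(0, sigma^2); the
# network's joint distribution is multivariate normal. Fitting and scoring
# run off the ML moment statistics (mean vector and covariance with
# denominator n), so score evaluations are O(k^3) in the family size only.

#' Moment sufficient statistics of a data matrix
#'
#' Column means and the maximum-likelihood covariance (denominator `n`) of
#' a numeric matrix. All fitting and scoring in the package consumes this
#' object, so it is computed once per dataset.
#'
#' @param x Numeric matrix, one row per observation, named columns.
#' @return List with `n`, `mean`, `cov` (ML covariance), `nodes`.
#' @export
moment_stats <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("data contain non-finite values")
  n <- nrow(x)
  if (n < 1) stop("data have zero rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  list(n = n, mean = mu, cov = crossprod(xc) / n, nodes = colnames(x))
}

as_moment_stats <- function(data) {
  if (is.list(data) && !is.data.frame(data) && all(c("n", "mean", "cov") %in% names(data)))
    return(data)
  moment_stats(data)
}

# internal: ML regression of child on parents from moment stats.
# Returns list(beta, intercept, sigma2). sigma2 uses denominator n.
ml_family_fit <- function(stats, child, parents) {
  S <- stats$cov
  if (!length(parents)) {
    return(list(beta = numeric(0), intercept = unname(stats$mean[child]),
                sigma2 = max(S[child, child], 0)))
  }
  Spp <- S[parents, parents, drop = FALSE]
  Spc <- S[parents, child]
  beta <- tryCatch(solve(Spp, Spc), error = function(e)
    stop("singular design fitting node '", child,
         "' (collinear or zero-variance parents)", call. = FALSE))
  sigma2 <- S[child, child] - sum(beta * Spc)
  if (sigma2 < -1e-8 * max(S[child, child], 1))
    stop("negative residual variance fitting node '", child, "'", call. = FALSE)
  # exact linear dependence leaves only cancellation error: snap to zero
  if (sigma2 < 1e-12 * max(S[child, child], .Machine$double.eps)) sigma2 <- 0
  list(beta = stats::setNames(as.numeric(beta), parents),
       intercept = unname(stats$mean[child] - sum(beta * stats$mean[parents])),
       sigma2 = max(sigma2, 0))
}

#' Fit linear-Gaussian CPDs by maximum likelihood
#'
#' Given a DAG and data, fits each node's conditional c + beta' parents by
#' ordinary least squares (the Gaussian MLE) and the residual standard
#' deviation with the maximum-likelihood denominator `n`. Orphan nodes get
#' their sample mean and ML standard deviation.
#'
#' @param dag A [new_dag()].
#' @param data Numeric matrix with columns named after the DAG's nodes, or
#'   a [moment_stats()] object.
#' @return Object of class `gbn`: `dag` plus one CPD per node (`child`,
#'   `parents`, `beta`, `intercept`, `sigma`).
#' @export
fit_parameters <- function(dag, data) {
  stats <- as_moment_stats(data)
  miss <- setdiff(dag$nodes, stats$nodes)
  if (length(miss)) stop("data lack columns for nodes: ", paste(miss, collapse = ", "))
  maxdeg <- if (nrow(dag$arcs)) max(table(dag$arcs[, 2])) else 0
  if (stats$n <= maxdeg + 1)
    stop("need more rows than the largest in-degree plus one (n = ", stats$n, ")")
  cpds <- lapply(dag$nodes, function(node) {
    ps <- parents_of(dag, node)
    f <- ml_family_fit(stats, node, ps)
    structure(list(child = node, parents = ps, beta = f$beta,
                   intercept = f$intercept, sigma = sqrt(f$sigma2)),
              class = "lg_cpd")
  })
  names(cpds) <- dag$nodes
  structure(list(dag = dag, cpds = cpds), class = "gbn")
}

#' Construct a Gaussian network from explicit CPDs
#'
#' @param dag A [new_dag()].
#' @param cpds Named list (one entry per node) of lists with `parents`,
#'   `beta`, `intercept`, `sigma`; parents must match the DAG.
#' @return A `gbn` object.
#' @export
new_gbn <- function(dag, cpds) {
  stopifnot(setequal(names(cpds), dag$nodes))
  cpds <- lapply(dag$nodes, function(node) {
    cp <- cpds[[node]]
    ps <- parents_of(dag, node)
    cp_par <- if (is.null(cp$parents)) character(0) else cp$parents
    if (!setequal(cp_par, ps))
      stop("cpd parents for '", node, "' disagree with the DAG")
    beta <- stats::setNames(as.numeric(cp$beta[match(ps, cp_par)]), ps)
    if (length(ps) == 0) beta <- numeric(0)
    if (is.na(cp$sigma) || cp$sigma < 0) stop("sigma must be >= 0 for '", node, "'")
    structure(list(child = node, parents = ps, beta = beta,
                   intercept = as.numeric(cp$intercept),
                   sigma = as.numeric(cp$sigma)), class = "lg_cpd")
  })
  names(cpds) <- dag$nodes
  structure(list(dag = dag, cpds = cpds), class = "gbn")
}

#' @export
print.gbn <- function(x, ...) {
  cat("Linear-Gaussian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$arcs), "arcs\n")
  invisible(x)
}

#' Joint log density of one or more profiles under a network
#'
#' Sums, over nodes, the Gaussian log density of each child given its
#' parents; by the chain rule this equals the log of the joint multivariate
#' normal density.
#'
#' A node with `sigma = 0` is deterministic: a profile off its implied
#' value scores `-Inf`; a profile exactly on it has no finite joint
#' density, which is raised as an error (the caller decides how to treat a
#' degenerate model).
#'
#' @param network A `gbn`.
#' @param profile Numeric vector named by node, or a matrix with one row
#'   per profile and columns named by node.
#' @return Numeric vector of log densities (length = number of profiles).
#' @export
log_density <- function(network, profile) {
  x <- if (is.matrix(profile)) profile else
    matrix(profile, nrow = 1, dimnames = list(NULL, names(profile)))
  if (is.null(colnames(x))) stop("profile must be named by scale")
  miss <- setdiff(network$dag$nodes, colnames(x))
  if (length(miss)) stop("profile lacks scales: ", paste(miss, collapse = ", "))
  out <- numeric(nrow(x))
  for (cp in network$cpds) {
    mu <- rep(cp$intercept, nrow(x))
    if (length(cp$parents))
      mu <- mu + as.vector(x[, cp$parents, drop = FALSE] %*% cp$beta)
    if (cp$sigma == 0) {
      on_value <- x[, cp$child] == mu
      if (any(on_value))
        stop("degenerate density: node '", cp$child,
             "' has sigma = 0 and the profile sits on its deterministic value")
      out <- out + ifelse(on_value, NA_real_, -Inf)
    } else {
      out <- out + stats::dnorm(x[, cp$child], mean = mu, sd = cp$sigma, log = TRUE)
    }
  }
  unname(out)
}

#' Closed-form joint multivariate normal of a network
#'
#' Solves the linear system x = c + B x + eps in topological order:
#' mean = (I - B)^-1 c and covariance = (I - B)^-1 D (I - B)^-T with
#' D = diag(sigma^2). The result is reported in the DAG's declared
#' (canonical) node order.
#'
#' @param network A `gbn`.
#' @return Object of class `mvn_joint`: `nodes`, `mean`, `sigma`.
#' @export
to_joint_mvn <- function(network) {
  nodes <- network$dag$nodes
  ord <- topological_order(network$dag)
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(ord, ord))
  cvec <- numeric(p)
  dvec <- numeric(p)
  names(cvec) <- names(dvec) <- ord
  for (cp in network$cpds) {
    if (length(cp$parents)) B[cp$child, cp$parents] <- cp$beta
    cvec[cp$child] <- cp$intercept
    dvec[cp$child] <- cp$sigma^2
  }
  IB <- diag(p) - B
  Ainv <- solve(IB)                 # triangular in topological order
  mu <- as.vector(Ainv %*% cvec)
  Sigma <- Ainv %*% diag(dvec, p) %*% t(Ainv)
  Sigma <- (Sigma + t(Sigma)) / 2
  names(mu) <- ord
  dimnames(Sigma) <- list(ord, ord)
  structure(list(nodes = nodes, mean = mu[nodes],
                 sigma = Sigma[nodes, nodes, drop = FALSE]),
            class = "mvn_joint")
}

#' @export
print.mvn_joint <- function(x, ...) {
  cat("Multivariate normal over", length(x$nodes), "scales\n")
  invisible(x)
}

# internal environment-backed cache of local BIC scores for one dataset
new_score_cache <- function() new.env(parent = emptyenv())

# internal: local (per-family) BIC contribution, higher is better.
# k = #parents + 2 free parameters (slopes + intercept + variance).
local_bic <- function(stats, child, parents, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  f <- ml_family_fit(stats, child, parents)
  if (f$sigma2 <= 0)
    stop("zero residual variance at node '", child,
         "': BIC is unbounded (deterministic family)", call. = FALSE)
  n <- stats$n
  ll <- -n / 2 * (log(2 * pi * f$sigma2) + 1)
  val <- ll - (length(parents) + 2) / 2 * log(n)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Network BIC score (penalized log-likelihood, higher is better)
#'
#' Sum over nodes of the family's maximized Gaussian log-likelihood minus
#' (k/2) log n with k = #parents + 2 (slopes, intercept, residual
#' variance). The score decomposes over families, which is what makes
#' greedy search and arc strength cheap.
#'
#' @param dag A [new_dag()].
#' @param data Data matrix or [moment_stats()].
#' @param cache Optional cache environment from `new_score_cache()`.
#' @return Scalar score.
#' @export
bic_score <- function(dag, data, cache = NULL) {
  stats <- as_moment_stats(data)
  sum(vapply(dag$nodes, function(node)
    local_bic(stats, node, parents_of(dag, node), cache), numeric(1)))
}

#' Arc strength as BIC score drop
#'
#' For each arc, the change in network BIC when the arc is removed:
#' `strength = bic(dag) - bic(dag without arc)`. Positive values mean the
#' arc improves the score; used to scale arc thickness when rendering.
#'
#' @param dag A [new_dag()].
#' @param data Data matrix or [moment_stats()].
#' @return Named numeric vector, names `"from->to"`, one entry per arc.
#' @export
arc_strength <- function(dag, data) {
  stats <- as_moment_stats(data)
  cache <- new_score_cache()
  out <- numeric(nrow(dag$arcs))
  nm <- character(nrow(dag$arcs))
  for (i in seq_len(nrow(dag$arcs))) {
    from <- dag$arcs[i, 1]; to <- dag$arcs[i, 2]
    ps <- parents_of(dag, to)
    out[i] <- local_bic(stats, to, ps, cache) -
      local_bic(stats, to, setdiff(ps, from), cache)
    nm[i] <- paste0(from, "->", to)
  }
  stats::setNames(out, nm)
}
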