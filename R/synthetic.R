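# Synthetic generators: random DAGs and networks for property testing, and
# a calibrated two-group MMPI-2-like study generator that emulates the
# cohort the pipeline was designed for (matched groups of 714, published
# marginal T-score moments, and group-specific dependence structure).

#' Random DAG by ordered edge sampling
#'
#' Samples a uniform node permutation, then includes each forward pair
#' independently with probability `expected_arcs / choose(p, 2)`, so the
#' result is acyclic by construction and the arc count is binomial with
#' the requested mean.
#'
#' @param p Number of nodes (names default to `X1..Xp`).
#' @param expected_arcs Mean number of arcs, in `[0, p(p-1)/2]`.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param nodes Optional node names.
#' @return A [new_dag()].
#' @export
make_random_dag <- function(p, expected_arcs, seed = NULL, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("X", seq_len(p))
  stopifnot(p >= 1, length(nodes) == p)
  npairs <- p * (p - 1) / 2
  stopifnot(expected_arcs >= 0, expected_arcs <= npairs)
  run <- function() {
    ord <- sample(nodes)
    arcs <- NULL
    if (p >= 2) {
      prob <- expected_arcs / npairs
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        if (stats::runif(1) < prob) arcs <- rbind(arcs, c(ord[i], ord[j]))
      }
    }
    new_dag(nodes, arcs)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Random linear-Gaussian parameters on a DAG
#'
#' Coefficient magnitudes uniform in `coef_range` with random sign,
#' residual SDs uniform in `sd_range`, intercepts 0.
#'
#' @param dag A [new_dag()].
#' @param coef_range,sd_range Length-2 numeric ranges.
#' @param seed Optional integer seed.
#' @return A `gbn`.
#' @export
make_random_network <- function(dag, coef_range = c(0.3, 0.9),
                                sd_range = c(0.5, 1.5), seed = NULL) {
  run <- function() {
    cpds <- lapply(dag$nodes, function(node) {
      ps <- parents_of(dag, node)
      beta <- stats::setNames(
        stats::runif(length(ps), coef_range[1], coef_range[2]) *
          sample(c(-1, 1), length(ps), replace = TRUE), ps)
      list(parents = ps, beta = beta, intercept = 0,
           sigma = stats::runif(1, sd_range[1], sd_range[2]))
    })
    names(cpds) <- dag$nodes
    new_gbn(dag, cpds)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Forward (ancestral) sampling from a network
#'
#' Draws each node in topological order from its linear-Gaussian
#' conditional. Columns of the result follow the DAG's declared canonical
#' order regardless of the topological order used internally.
#'
#' @param network A `gbn`.
#' @param n Number of rows.
#' @param seed Optional integer seed.
#' @return Numeric `n x p` matrix with named columns.
#' @export
ancestral_sample <- function(network, n, seed = NULL) {
  stopifnot(n >= 1)
  run <- function() {
    ord <- topological_order(network$dag)
    x <- matrix(0, n, length(ord), dimnames = list(NULL, ord))
    for (node in ord) {
      cp <- network$cpds[[node]]
      mu <- rep(cp$intercept, n)
      if (length(cp$parents))
        mu <- mu + as.vector(x[, cp$parents, drop = FALSE] %*% cp$beta)
      x[, node] <- mu + if (cp$sigma > 0) stats::rnorm(n, 0, cp$sigma) else 0
    }
    x[, network$dag$nodes, drop = FALSE]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# standardized arc coefficients of the preset networks; chosen so the
# implied pairwise correlations hit the published group-specific values
# (Pt-D 0.74/0.29, Pd-Ma 0.61/0.41, F-Hs 0.55/0.63) exactly, given that
# each arc's parents are mutually independent in these structures.
.preset_coefs <- function(group = c("healthy", "schizophrenia")) {
  group <- match.arg(group)
  shared <- list(
    c("L", "K", 0.50),
    c("K", "Hy", 0.40),
    c("Hs", "Hy", 0.50),
    c("Pt", "Sc", if (group == "healthy") 0.60 else 0.50),
    c("F", "Sc", if (group == "healthy") 0.50 else 0.25),
    c("D", "Si", 0.55),
    c("Pd", "Pt", 0.45)
  )
  extra <- if (group == "healthy") list(
    c("D", "Pt", 0.74),   # strong coupling present only in healthy adults
    c("Pd", "Ma", 0.61),
    c("F", "Hs", 0.55)
  ) else list(
    c("Hs", "Sc", 0.45),  # Sc-Hs arc specific to the patient group
    c("F", "Hs", 0.63),
    c("D", "Pt", 0.29),   # attenuated residual coupling in patients
    c("Pd", "Ma", 0.41)
  )
  arcs <- c(shared, extra)
  data.frame(from = vapply(arcs, `[`, "", 1),
             to = vapply(arcs, `[`, "", 2),
             coef = as.numeric(vapply(arcs, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

# internal: build a unit-marginal-variance network from standardized arc
# coefficients, then rescale each marginal to (mean, sd).
calibrated_network <- function(coefs, means, sds) {
  nodes <- mmpi_scales()
  dag <- new_dag(nodes, as.matrix(coefs[, c("from", "to")]))
  ord <- topological_order(dag)
  # residual variances that make every marginal variance exactly 1
  Sigma <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  sig2 <- stats::setNames(numeric(length(nodes)), nodes)
  for (node in ord) {
    ps <- parents_of(dag, node)
    b <- stats::setNames(rep(0, length(ps)), ps)
    if (length(ps)) {
      sel <- coefs$to == node
      b[coefs$from[sel]] <- coefs$coef[sel]
      v_lin <- as.numeric(t(b) %*% Sigma[ps, ps, drop = FALSE] %*% b)
    } else v_lin <- 0
    if (v_lin >= 1) stop("preset coefficients imply variance >= 1 at ", node)
    sig2[node] <- 1 - v_lin
    # update implied covariance row/col for this node
    if (length(ps)) {
      cov_with <- Sigma[, ps, drop = FALSE] %*% b
      Sigma[, node] <- cov_with
      Sigma[node, ] <- cov_with
    }
    Sigma[node, node] <- 1
  }
  cpds <- lapply(nodes, function(node) {
    ps <- parents_of(dag, node)
    bz <- stats::setNames(rep(0, length(ps)), ps)
    if (length(ps)) {
      sel <- coefs$to == node
      bz[coefs$from[sel]] <- coefs$coef[sel]
    }
    # affine rescale z -> mean + sd * z of every marginal
    beta <- bz * sds[node] / sds[ps]
    list(parents = ps, beta = beta,
         intercept = means[node] - sum(beta * means[ps]),
         sigma = sds[node] * sqrt(sig2[node]))
  })
  names(cpds) <- nodes
  new_gbn(dag, cpds)
}

#' Calibrated two-group MMPI-2 network preset
#'
#' A fixed pair of 13-node linear-Gaussian networks over the canonical
#' scales emulating the dependence structure reported for matched healthy
#' and schizophrenia groups: seven arcs shared by both groups (L-K, K-Hy,
#' Hs-Hy, Sc-Pt, F-Sc, Si-D, Pd-Pt), strong D-Pt, Pd-Ma and F-Hs coupling
#' in the healthy network, an Hs-Sc arc only in the patient network, and
#' weak D-Pt / Pd-Ma arcs in the patient network carrying the residual
#' correlation that the full (unpublished) patient structure transmits
#' through arcs not named in print. Implied correlations: Pt-D 0.74 vs
#' 0.29, Pd-Ma 0.61 vs 0.41, F-Hs 0.55 vs 0.63. Marginal means and SDs
#' match [mmpi_tscore_moments()] exactly. Arc orientations follow the
#' canonical scale order (earlier scale -> later scale).
#'
#' @return List with elements `healthy` and `schizophrenia`, each a `gbn`.
#' @export
mmpi2_preset <- function() {
  mom <- mmpi_tscore_moments()
  list(
    healthy = calibrated_network(.preset_coefs("healthy"),
                                 mom[, "mean_healthy"], mom[, "sd_healthy"]),
    schizophrenia = calibrated_network(.preset_coefs("schizophrenia"),
                                       mom[, "mean_schizophrenia"],
                                       mom[, "sd_schizophrenia"])
  )
}

#' Study configuration for the synthetic two-group cohort
#'
#' Defaults emulate the matched study design: 714 participants per group,
#' age about N(28, 12^2) truncated to 16-70 years, 75% male, education
#' about N(11.4, 3.4^2) years truncated at 0, 30% married. The
#' `age_confounding` knob shifts the patient group's mean age (years) to
#' exercise propensity matching.
#'
#' @param n_per_group Participants per diagnostic group (the patient group
#'   size).
#' @param age_confounding Additive age shift (years) applied to group 1.
#' @param healthy_pool_ratio Healthy-to-patient size ratio of the
#'   generated cohort; 1 (default) yields a balanced analysis cohort,
#'   larger values emulate the oversized healthy screening pool from which
#'   propensity matching selects controls.
#' @param networks List with `healthy` and `schizophrenia` `gbn`s;
#'   defaults to [mmpi2_preset()].
#' @return List of class `study_config`.
#' @export
study_config <- function(n_per_group = 714, age_confounding = 0,
                         healthy_pool_ratio = 1,
                         networks = mmpi2_preset()) {
  stopifnot(n_per_group >= 2, healthy_pool_ratio >= 1)
  structure(list(
    n_per_group = n_per_group,
    age_confounding = age_confounding,
    healthy_pool_ratio = healthy_pool_ratio,
    networks = networks,
    age_mean = 28, age_sd = 12, age_range = c(16, 70),
    p_male = 0.75,
    edu_mean = 11.4, edu_sd = 3.4,
    p_married = 0.30
  ), class = "study_config")
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Simulate a two-group MMPI-2-like cohort
#'
#' Samples `n_per_group` profiles from each group's network, attaches
#' demographics (shared distributions, plus the configured age
#' confounding in the patient group) and binary diagnosis labels
#' (1 = schizophrenia).
#'
#' @param config A [study_config()].
#' @param seed Optional integer seed.
#' @return Object of class `mmpi_cohort`: `profiles` (matrix, canonical
#'   column order), `labels` (integer 0/1), `demographics` (data.frame
#'   with `age`, `gender`, `education`, `marital`).
#' @export
make_two_group_study <- function(config = study_config(), seed = NULL) {
  run <- function() {
    n1 <- config$n_per_group
    n0 <- round(config$healthy_pool_ratio * n1)
    x0 <- ancestral_sample(config$networks$healthy, n0)
    x1 <- ancestral_sample(config$networks$schizophrenia, n1)
    demog <- function(n, shift) data.frame(
      age = rtruncnorm1(n, config$age_mean + shift, config$age_sd,
                        config$age_range[1], config$age_range[2]),
      gender = stats::rbinom(n, 1, config$p_male),
      education = rtruncnorm1(n, config$edu_mean, config$edu_sd, lo = 0),
      marital = stats::rbinom(n, 1, config$p_married)
    )
    new_cohort(profiles = rbind(x0, x1),
               labels = rep(c(0L, 1L), c(n0, n1)),
               demographics = rbind(demog(n0, 0),
                                    demog(n1, config$age_confounding)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct a cohort object
#'
#' @param profiles Numeric matrix of T-scores, columns named by scale.
#' @param labels Integer 0/1 vector (1 = schizophrenia).
#' @param demographics Data frame with columns `age`, `gender`,
#'   `education`, `marital`; optional.
#' @return An `mmpi_cohort`.
#' @export
new_cohort <- function(profiles, labels, demographics = NULL) {
  profiles <- as.matrix(profiles)
  if (!all(is.finite(profiles))) stop("profiles contain non-finite values")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (nrow(profiles) != length(labels)) stop("row counts disagree")
  if (!is.null(demographics)) {
    demographics <- as.data.frame(demographics)
    if (nrow(demographics) != length(labels)) stop("row counts disagree")
  }
  structure(list(profiles = profiles, labels = labels,
                 demographics = demographics), class = "mmpi_cohort")
}

#' @export
print.mmpi_cohort <- function(x, ...) {
  cat("MMPI-2 cohort:", nrow(x$profiles), "participants (",
      sum(x$labels == 0), "healthy /", sum(x$labels == 1),
      "schizophrenia ),", ncol(x$profiles), "scales\n")
  invisible(x)
}

#' Subset a cohort by row index
#' @param cohort An `mmpi_cohort`.
#' @param idx Integer row indices.
#' @return The subsetted `mmpi_cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  new_cohort(cohort$profiles[idx, , drop = FALSE], cohort$labels[idx],
             if (!is.null(cohort$demographics))
               cohort$demographics[idx, , drop = FALSE])
}
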