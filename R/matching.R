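# Propensity-score matching of the two diagnostic groups on demographics.
# A main-effects logistic model supplies the scores; pairing is greedy
# nearest-neighbor 1:1 without replacement on the logit scale with a
# caliper, which yields the balanced two-group cohort the downstream
# network analysis needs.

#' Propensity scores from a main-effects logistic model
#'
#' Models P(label = 1 | age, gender, education, marital) by logistic
#' regression. The fit is invariant to row order.
#'
#' @param demographics Data frame with columns `age`, `gender`,
#'   `education`, `marital`.
#' @param labels Integer 0/1 vector.
#' @return Numeric vector of fitted probabilities in (0, 1).
#' @export
estimate_propensity <- function(demographics, labels) {
  need <- c("age", "gender", "education", "marital")
  miss <- setdiff(need, names(demographics))
  if (length(miss)) stop("demographics lack columns: ", paste(miss, collapse = ", "))
  if (anyNA(demographics[need])) stop("missing covariate values are not supported")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  df <- cbind(demographics[need], .y = labels)
  fit <- suppressWarnings(
    stats::glm(.y ~ age + gender + education + marital, data = df,
               family = stats::binomial()))
  ps <- as.numeric(stats::fitted(fit))
  eps <- 1e-8
  if (any(ps < eps) || any(ps > 1 - eps))
    stop("(quasi-)perfect separation in the propensity model; ",
         "match on exact covariates or drop the offending covariate")
  ps
}

#' Greedy nearest-neighbor 1:1 propensity matching
#'
#' Pairs each treated (label 1) row with the nearest unmatched control on
#' the logit of the propensity score, within a caliper expressed in SDs of
#' the pooled logit scores. Treated rows are processed in descending score
#' order; ties in distance go to the smallest control index, so the result
#' is deterministic.
#'
#' @param scores Propensity scores in (0, 1) (see [estimate_propensity()]).
#' @param labels Integer 0/1 vector.
#' @param caliper Maximum within-pair logit distance, in SD units of the
#'   logit scores; `caliper = 0` allows only exact-score ties.
#' @return List of class `match_result`: `pairs` (two-column matrix of row
#'   indices, control then treated), `propensity`, `unmatched`, `caliper_abs`.
#' @export
match_cohort <- function(scores, labels, caliper = 0.2) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(scores > 0 & scores < 1))
  if (!any(labels == 1) || !any(labels == 0)) stop("both classes must be present")
  lg <- stats::qlogis(scores)
  sd_lg <- stats::sd(lg)
  cal_abs <- if (is.finite(sd_lg) && sd_lg > 0) caliper * sd_lg else caliper
  treated <- which(labels == 1)
  treated <- treated[order(-scores[treated], treated)]
  controls <- which(labels == 0)
  taken <- rep(FALSE, length(controls))
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("control", "treated")))
  for (t in treated) {
    free <- which(!taken)
    if (!length(free)) break
    d <- abs(lg[controls[free]] - lg[t])
    best <- free[order(d, controls[free])[1]]
    if (d[order(d, controls[free])[1]] <= cal_abs + 1e-12) {
      taken[best] <- TRUE
      pairs <- rbind(pairs, c(controls[best], t))
    }
  }
  matched <- c(pairs)
  structure(list(pairs = pairs, propensity = scores,
                 unmatched = setdiff(seq_along(labels), matched),
                 caliper_abs = cal_abs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Propensity matching:", nrow(x$pairs), "pairs,",
      length(x$unmatched), "unmatched rows\n")
  invisible(x)
}

#' Standardized mean difference of a covariate between groups
#'
#' (mean1 - mean0) / sqrt((var1 + var0) / 2), the conventional balance
#' diagnostic.
#'
#' @param x Numeric covariate.
#' @param labels Integer 0/1 vector.
#' @return Scalar SMD (signed).
#' @export
standardized_mean_diff <- function(x, labels) {
  labels <- as.integer(labels)
  m1 <- mean(x[labels == 1]); m0 <- mean(x[labels == 0])
  v1 <- stats::var(x[labels == 1]); v0 <- stats::var(x[labels == 0])
  pooled <- sqrt((v1 + v0) / 2)
  if (pooled == 0) return(0)
  (m1 - m0) / pooled
}

#' Pre/post-matching covariate balance table
#'
#' @param cohort An `mmpi_cohort` with demographics.
#' @param match A [match_cohort()] result.
#' @return Data frame with one row per covariate and columns `smd_pre`,
#'   `smd_post`.
#' @export
balance_table <- function(cohort, match) {
  need <- c("age", "gender", "education", "marital")
  keep <- c(match$pairs)
  out <- data.frame(covariate = need, smd_pre = NA_real_, smd_post = NA_real_)
  for (i in seq_along(need)) {
    v <- cohort$demographics[[need[i]]]
    out$smd_pre[i] <- standardized_mean_diff(v, cohort$labels)
    out$smd_post[i] <- standardized_mean_diff(v[keep], cohort$labels[keep])
  }
  out
}

#' Match a cohort end to end
#'
#' Convenience wrapper: estimates propensity scores, matches, and returns
#' the matched cohort together with the balance table.
#'
#' @param cohort An `mmpi_cohort` with demographics.
#' @param caliper Passed to [match_cohort()].
#' @return List with `cohort` (matched rows only), `match`, `balance`.
#' @export
match_study <- function(cohort, caliper = 0.2) {
  ps <- estimate_propensity(cohort$demographics, cohort$labels)
  mr <- match_cohort(ps, cohort$labels, caliper = caliper)
  keep <- sort(c(mr$pairs))
  list(cohort = cohort_subset(cohort, keep), match = mr,
       balance = balance_table(cohort, mr))
}
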