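# The dual-network generative classifier: one linear-Gaussian network per
# diagnostic group, a new profile classified by the log likelihood ratio
# of the two fitted joints (plus the training log prior odds), evaluated
# by repeated random shuffle-split cross-validation.

#' Fit the dual-network classifier
#'
#' Learns a structure and fits parameters independently within each label
#' stratum, and stores the training log prior odds
#' `log(n_healthy / n_schizophrenia)` (0 under a matched design).
#'
#' @param train An `mmpi_cohort` containing both classes.
#' @param alpha Significance level for structure learning.
#' @param max_sepset,max_iter Passed to [learn_structure()].
#' @return Object of class `dual_bn`: `net_healthy`, `net_schiz`,
#'   `log_prior_odds`.
#' @export
fit_classifier <- function(train, alpha = 0.05, max_sepset = 3, max_iter = 200L) {
  n0 <- sum(train$labels == 0); n1 <- sum(train$labels == 1)
  if (n0 < 15 || n1 < 15)
    stop("stratum too small to fit a 13-node network (healthy ", n0,
         ", schizophrenia ", n1, ")")
  fit_one <- function(x) {
    dag <- learn_structure(x, alpha = alpha, max_sepset = max_sepset,
                           max_iter = max_iter)
    fit_parameters(dag, x)
  }
  structure(list(
    net_healthy = fit_one(train$profiles[train$labels == 0, , drop = FALSE]),
    net_schiz = fit_one(train$profiles[train$labels == 1, , drop = FALSE]),
    log_prior_odds = log(n0 / n1)
  ), class = "dual_bn")
}

#' @export
print.dual_bn <- function(x, ...) {
  cat("Dual-network classifier: healthy", nrow(x$net_healthy$dag$arcs),
      "arcs, schizophrenia", nrow(x$net_schiz$dag$arcs),
      "arcs, log prior odds", format(x$log_prior_odds, digits = 4), "\n")
  invisible(x)
}

#' Log likelihood-ratio score of profiles
#'
#' `log p(x | healthy) - log p(x | schizophrenia) + log_prior_odds`;
#' positive favors the healthy group.
#'
#' @param model A [fit_classifier()] result (or any list with
#'   `net_healthy`, `net_schiz`, `log_prior_odds`).
#' @param profile Named numeric vector, or matrix with one row per profile.
#' @return Numeric score(s).
#' @export
score_profile <- function(model, profile) {
  log_density(model$net_healthy, profile) -
    log_density(model$net_schiz, profile) + model$log_prior_odds
}

#' Classify profiles by thresholded score
#'
#' @inheritParams score_profile
#' @param threshold Decision threshold on the score; an exact tie goes to
#'   healthy.
#' @return Integer labels (0 = healthy, 1 = schizophrenia).
#' @export
classify_profile <- function(model, profile, threshold = 0) {
  as.integer(score_profile(model, profile) < threshold)
}

#' Classification metrics: accuracy, F1, AUC
#'
#' F1 takes schizophrenia (label 1) as the positive class. AUC uses the
#' rank (Mann-Whitney) formulation on `scores`, which must be oriented so
#' larger values favor the positive class; tied scores are credited 0.5.
#'
#' @param predicted Integer 0/1 predictions.
#' @param scores Numeric scores, larger = more schizophrenia-like.
#' @param truth Integer 0/1 true labels.
#' @return Named numeric vector `accuracy`, `f1`, `auc`.
#' @export
compute_metrics <- function(predicted, scores, truth) {
  stopifnot(length(predicted) == length(truth), length(scores) == length(truth))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  acc <- mean(predicted == truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = acc, f1 = f1, auc = rank_auc(scores, truth))
}

#' Rank-based AUC with ties credited one half
#'
#' @param scores Numeric scores, larger = more positive-class-like.
#' @param truth Integer 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: both classes must be present in the truth")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Random shuffle-split cross-validation of the dual-network classifier
#'
#' Per iteration: a stratified random `train_frac` / `1 - train_frac`
#' split, [fit_classifier()] on the training part (structure re-learned
#' every time, so no information leaks from test to train), metrics on the
#' held-out part. Reports the mean and SD of each metric.
#'
#' @param cohort An `mmpi_cohort` with both classes.
#' @param iterations Number of random splits.
#' @param train_frac Training fraction per stratum.
#' @param alpha Structure-learning significance level.
#' @param seed Integer seed; the whole report is reproducible from it.
#' @return Object of class `eval_report` with `accuracy_mean/sd`,
#'   `f1_mean/sd`, `auc_mean/sd`, `iterations`, `per_iteration` (matrix).
#' @export
evaluate_rsscv <- function(cohort, iterations = 100, train_frac = 0.8,
                           alpha = 0.05, seed = 1L) {
  rsscv_engine(cohort, iterations, train_frac, seed, function(train, test) {
    model <- fit_classifier(train, alpha = alpha)
    sc <- -score_profile(model, test$profiles)  # larger = schizophrenia
    compute_metrics(as.integer(sc > 0), sc, test$labels)
  })
}

#' Logistic-regression baseline on scales D, Pt, Sc
#'
#' The comparison model: logistic regression of the diagnosis on the three
#' "Scale 278" T-scores (D, Pt, Sc), evaluated under the identical
#' shuffle-split protocol as [evaluate_rsscv()].
#'
#' @inheritParams evaluate_rsscv
#' @return An `eval_report`.
#' @export
baseline_scale278 <- function(cohort, iterations = 100, train_frac = 0.8,
                              seed = 1L) {
  stopifnot(all(c("D", "Pt", "Sc") %in% colnames(cohort$profiles)))
  rsscv_engine(cohort, iterations, train_frac, seed, function(train, test) {
    df <- data.frame(y = train$labels,
                     D = train$profiles[, "D"],
                     Pt = train$profiles[, "Pt"],
                     Sc = train$profiles[, "Sc"])
    fit <- suppressWarnings(stats::glm(y ~ D + Pt + Sc, data = df,
                                       family = stats::binomial()))
    nd <- data.frame(D = test$profiles[, "D"], Pt = test$profiles[, "Pt"],
                     Sc = test$profiles[, "Sc"])
    pr <- as.numeric(stats::predict(fit, newdata = nd, type = "response"))
    compute_metrics(as.integer(pr > 0.5), pr, test$labels)
  })
}

# internal: shared stratified shuffle-split protocol
rsscv_engine <- function(cohort, iterations, train_frac, seed, fit_and_score) {
  stopifnot(iterations >= 1, train_frac > 0, train_frac < 1)
  if (!any(cohort$labels == 0) || !any(cohort$labels == 1))
    stop("cohort must contain both classes")
  idx0 <- which(cohort$labels == 0)
  idx1 <- which(cohort$labels == 1)
  res <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(iterations), function(it) {
      tr0 <- sample(idx0, floor(train_frac * length(idx0)))
      tr1 <- sample(idx1, floor(train_frac * length(idx1)))
      tr <- sort(c(tr0, tr1))
      te <- setdiff(seq_along(cohort$labels), tr)
      m <- tryCatch(
        fit_and_score(cohort_subset(cohort, tr), cohort_subset(cohort, te)),
        error = function(e) stop("iteration ", it, " failed: ",
                                 conditionMessage(e), call. = FALSE))
      m
    }, numeric(3))
  })
  msd <- function(v) if (length(v) > 1) stats::sd(v) else 0
  structure(list(
    accuracy_mean = mean(res["accuracy", ]), accuracy_sd = msd(res["accuracy", ]),
    f1_mean = mean(res["f1", ]), f1_sd = msd(res["f1", ]),
    auc_mean = mean(res["auc", ]), auc_sd = msd(res["auc", ]),
    iterations = iterations, per_iteration = res
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(m, s) sprintf("%.3f (%.3f)", m, s)
  cat(sprintf("%d-iteration shuffle-split evaluation\n", x$iterations))
  cat("  accuracy:", fmt(x$accuracy_mean, x$accuracy_sd), "\n")
  cat("  F1:      ", fmt(x$f1_mean, x$f1_sd), "\n")
  cat("  AUC:     ", fmt(x$auc_mean, x$auc_sd), "\n")
  invisible(x)
}
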