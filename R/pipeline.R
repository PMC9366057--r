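# End-to-end pipeline: match -> learn (per group) -> evaluate ->
# compare correlations -> what-if, with every artifact written to disk
# and a manifest recording the configuration and seed.

#' Pipeline configuration
#'
#' @param input Cohort CSV path, or an `mmpi_cohort` object.
#' @param out_dir Output directory (created if absent).
#' @param alpha Structure-learning significance level.
#' @param iterations Shuffle-split iterations for evaluation.
#' @param train_frac Training fraction per split.
#' @param n_perm Label permutations for the correlation test.
#' @param whatif_n Clamp draws per scale in the what-if table.
#' @param caliper Matching caliper (logit SD units).
#' @param seed Integer seed driving every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, alpha = 0.05, iterations = 100,
                            train_frac = 0.8, n_perm = 10000,
                            whatif_n = 1000, caliper = 0.2, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, iterations >= 1,
            train_frac > 0, train_frac < 1, n_perm >= 1, whatif_n >= 1,
            caliper >= 0)
  structure(list(input = input, out_dir = out_dir, alpha = alpha,
                 iterations = iterations, train_frac = train_frac,
                 n_perm = n_perm, whatif_n = whatif_n, caliper = caliper,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dual-network analysis pipeline
#'
#' Stages: propensity matching (skipped, with a note, when the cohort has
#' no demographics), per-group structure learning and fitting,
#' shuffle-split evaluation of the dual-network classifier plus the
#' D/Pt/Sc logistic baseline, the correlation-matrix permutation test,
#' and the what-if table. All artifacts (networks as JSON + GraphML, the
#' evaluation report, the correlation comparison, the what-if table and a
#' run manifest) are written under `config$out_dir`. Identical
#' config + seed produces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory results (`cohort`, `balance`,
#'   `networks`, `evaluation`, `baseline`, `correlation`, `whatif`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (inherits(config$input, "mmpi_cohort")) config$input
    else read_cohort_csv(config$input)
  })
  if (!any(cohort$labels == 0) || !any(cohort$labels == 1))
    stop("pipeline stage 'input' failed: cohort must contain both classes")

  balance <- NULL
  if (!is.null(cohort$demographics)) {
    ms <- stage("match", match_study(cohort, caliper = config$caliper))
    cohort <- ms$cohort
    balance <- ms$balance
    utils::write.csv(balance, file.path(config$out_dir, "balance.csv"),
                     row.names = FALSE)
  }

  nets <- stage("learn", {
    fit_group <- function(lbl) {
      x <- cohort$profiles[cohort$labels == lbl, , drop = FALSE]
      dag <- learn_structure(x, alpha = config$alpha)
      list(net = fit_parameters(dag, x), strength = arc_strength(dag, x))
    }
    list(healthy = fit_group(0L), schizophrenia = fit_group(1L))
  })
  for (g in names(nets)) {
    save_network(nets[[g]]$net, file.path(config$out_dir, paste0("network_", g, ".json")))
    export_graphml(nets[[g]]$net$dag,
                   file.path(config$out_dir, paste0("network_", g, ".graphml")),
                   strength = nets[[g]]$strength)
  }

  evaluation <- stage("evaluate",
    evaluate_rsscv(cohort, iterations = config$iterations,
                   train_frac = config$train_frac, alpha = config$alpha,
                   seed = config$seed))
  baseline <- stage("evaluate",
    baseline_scale278(cohort, iterations = config$iterations,
                      train_frac = config$train_frac, seed = config$seed))
  jsonlite::write_json(
    list(dual_network = unclass(evaluation)[c("accuracy_mean", "accuracy_sd",
                                              "f1_mean", "f1_sd",
                                              "auc_mean", "auc_sd", "iterations")],
         scale278_baseline = unclass(baseline)[c("accuracy_mean", "accuracy_sd",
                                                 "f1_mean", "f1_sd",
                                                 "auc_mean", "auc_sd", "iterations")]),
    file.path(config$out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  correlation <- stage("compare-correlations",
    permutation_equality_test(cohort$profiles[cohort$labels == 0, , drop = FALSE],
                              cohort$profiles[cohort$labels == 1, , drop = FALSE],
                              n_perm = config$n_perm, seed = config$seed))
  utils::write.csv(round(correlation$difference, 6),
                   file.path(config$out_dir, "correlation_difference.csv"))
  jsonlite::write_json(
    list(statistic = correlation$statistic, p_value = correlation$p_value,
         n_perm = correlation$n_perm, stat_name = correlation$stat_name),
    file.path(config$out_dir, "correlation_test.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  whatif <- stage("whatif",
    whatif_difference_table(nets$healthy$net, nets$schizophrenia$net,
                            n = config$whatif_n, seed = config$seed))
  utils::write.csv(as.data.frame(whatif$mean_diff),
                   file.path(config$out_dir, "whatif_mean_difference.csv"))

  manifest <- list(
    package = "mmpibn",
    package_version = as.character(utils::packageVersion("mmpibn")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "input")]),
    n_rows_analyzed = nrow(cohort$profiles),
    arcs_healthy = nrow(nets$healthy$net$dag$arcs),
    arcs_schizophrenia = nrow(nets$schizophrenia$net$dag$arcs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, balance = balance, networks = nets,
                 evaluation = evaluation, baseline = baseline,
                 correlation = correlation, whatif = whatif,
                 manifest = manifest))
}
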