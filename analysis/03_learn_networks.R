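#!/usr/bin/env Rscript
# Stage 3 — learn one Gaussian Bayesian network per diagnostic group.
#
# Hybrid structure learning (Fisher-z skeleton at alpha = 0.05, then BIC
# hill climbing restricted to the skeleton) runs separately on the healthy
# and patient strata of the matched cohort; parameters are then fitted by
# maximum likelihood. Arc strengths (BIC drop on deletion) are written as
# GraphML edge attributes for rendering.

library(mmpibn)

cohort <- read_cohort_csv("results/matched_cohort.csv")

for (grp in c(healthy = 0L, schizophrenia = 1L)) {
  name <- names(which(c(healthy = 0L, schizophrenia = 1L) == grp))
  x <- cohort$profiles[cohort$labels == grp, , drop = FALSE]
  dag <- learn_structure(x, alpha = 0.05)
  net <- fit_parameters(dag, x)
  st <- arc_strength(dag, x)
  save_network(net, sprintf("results/network_%s.json", name))
  export_graphml(dag, sprintf("results/network_%s.graphml", name), strength = st)
  export_dot(dag, sprintf("results/network_%s.dot", name))
  cat(sprintf("%s network: %d arcs; strongest dependencies:\n", name, nrow(dag$arcs)))
  print(round(sort(st, decreasing = TRUE)[1:5], 1))
}

# which adjacencies are group-specific?
pair_set <- function(path) {
  d <- load_network(path)$dag
  apply(d$arcs, 1, function(e) paste(sort(e), collapse = "-"))
}
h <- pair_set("results/network_healthy.json")
s <- pair_set("results/network_schizophrenia.json")
cat("Shared adjacencies:", paste(intersect(h, s), collapse = ", "), "\n")
cat("Healthy-only:", paste(setdiff(h, s), collapse = ", "), "\n")
cat("Schizophrenia-only:", paste(setdiff(s, h), collapse = ", "), "\n")
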