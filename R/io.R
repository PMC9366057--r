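# Cohort CSV input/output, JSON persistence of networks and classifier
# models, and graph export (GraphML / DOT) for standard viewers.

MODEL_FORMAT_VERSION <- "1.0"

#' Read a cohort from CSV
#'
#' Expects one row per participant: the 13 canonical scale columns (any
#' order; an optional `mapping` renames nonstandard headers), the
#' demographic columns and a `label` column. Missing or non-numeric cells
#' are rejected with the offending row/column.
#'
#' @param path CSV path with a header row.
#' @param mapping Optional named character vector `canonical = file_column`.
#' @return An `mmpi_cohort`.
#' @export
read_cohort_csv <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      i <- match(mapping[[canon]], names(df))
      if (is.na(i)) stop("mapped column not found: ", mapping[[canon]])
      names(df)[i] <- canon
    }
  }
  need <- c(mmpi_scales(), "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in mmpi_scales()) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("missing or non-numeric T-score at row ", bad[1], ", column ", col)
    df[[col]] <- v
  }
  demog_cols <- intersect(c("age", "gender", "education", "marital"), names(df))
  new_cohort(
    profiles = as.matrix(df[mmpi_scales()]),
    labels = df$label,
    demographics = if (length(demog_cols)) df[demog_cols]
  )
}

#' Write a cohort to CSV
#'
#' @param cohort An `mmpi_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort$profiles)
  if (!is.null(cohort$demographics)) df <- cbind(df, cohort$demographics)
  df$label <- cohort$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# internal: gbn <-> plain list (JSON-ready)
gbn_to_list <- function(network) {
  list(
    nodes = network$dag$nodes,
    arcs = apply(network$dag$arcs, 1, function(r) list(from = r[[1]], to = r[[2]])),
    cpds = lapply(unname(network$cpds), function(cp) list(
      child = cp$child, parents = cp$parents,
      beta = unname(as.numeric(cp$beta)),
      intercept = cp$intercept, sigma = cp$sigma))
  )
}

gbn_from_list <- function(obj) {
  arcs <- if (length(obj$arcs))
    do.call(rbind, lapply(obj$arcs, function(a) c(a$from, a$to)))
  dag <- new_dag(unlist(obj$nodes), arcs)
  cpds <- lapply(obj$cpds, function(cp) {
    ps <- as.character(unlist(cp$parents))
    list(parents = ps,
         beta = stats::setNames(as.numeric(unlist(cp$beta)), ps),
         intercept = as.numeric(cp$intercept), sigma = as.numeric(cp$sigma))
  })
  names(cpds) <- vapply(obj$cpds, function(cp) cp$child, "")
  new_gbn(dag, cpds)
}

#' Save / load a Gaussian network as JSON
#'
#' Round trips are exact for the structure and faithful to full double
#' precision for the parameters.
#'
#' @param network A `gbn`.
#' @param path JSON path.
#' @return `save_network`: `path` invisibly; `load_network`: a `gbn`.
#' @export
save_network <- function(network, path) {
  obj <- c(list(format = "mmpibn-network", version = MODEL_FORMAT_VERSION),
           gbn_to_list(network))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path)
  check_format(obj, "mmpibn-network")
  gbn_from_list(obj)
}

#' Save / load a dual-network classifier model as JSON
#'
#' The file records both group networks, the log prior odds and a format
#' version; loading checks the version and warns on unknown extra fields.
#'
#' @param model A [fit_classifier()] result.
#' @param path JSON path.
#' @return `save_model`: `path` invisibly; `load_model`: a `dual_bn`.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "mmpibn-model", version = MODEL_FORMAT_VERSION,
              log_prior_odds = model$log_prior_odds,
              net_healthy = gbn_to_list(model$net_healthy),
              net_schiz = gbn_to_list(model$net_schiz))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  check_format(obj, "mmpibn-model")
  known <- c("format", "version", "log_prior_odds", "net_healthy", "net_schiz")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning("ignoring unknown model fields: ", paste(extra, collapse = ", "))
  structure(list(net_healthy = gbn_from_list(obj$net_healthy),
                 net_schiz = gbn_from_list(obj$net_schiz),
                 log_prior_odds = as.numeric(obj$log_prior_odds)),
            class = "dual_bn")
}

check_format <- function(obj, expected) {
  if (!identical(obj$format, expected))
    stop("not a ", expected, " file")
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("unsupported ", expected, " version '", obj$version,
         "' (expected ", MODEL_FORMAT_VERSION, ")")
}

# internal: igraph object from a bn_dag, optionally with strength attr
dag_igraph <- function(dag, strength = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(dag$nodes), name = dag$nodes)
  if (nrow(dag$arcs)) {
    g <- igraph::add_edges(g, t(dag$arcs))
    if (!is.null(strength)) {
      key <- paste0(dag$arcs[, 1], "->", dag$arcs[, 2])
      igraph::E(g)$strength <- as.numeric(strength[key])
    }
  }
  g
}

#' Export a DAG to GraphML or DOT
#'
#' @param dag A [new_dag()].
#' @param path Output path.
#' @param strength Optional named arc-strength vector from
#'   [arc_strength()], written as edge attribute `strength`.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(dag, path, strength = NULL) {
  igraph::write_graph(dag_igraph(dag, strength), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_dot <- function(dag, path, strength = NULL) {
  igraph::write_graph(dag_igraph(dag, strength), path, format = "dot")
  invisible(path)
}
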