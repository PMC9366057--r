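#' Directed acyclic graph over named nodes
#'
#' Constructs a `bn_dag`: an ordered node set plus a set of directed arcs.
#' Arcs are validated against the node set, self-loops are rejected, and
#' acyclicity is enforced at construction time.
#'
#' @param nodes Character vector of node names (the canonical order used
#'   for deterministic tie-breaking throughout the package).
#' @param arcs Two-column character matrix (or data.frame) with columns
#'   `from`, `to`; may have zero rows.
#' @return An object of class `bn_dag` with elements `nodes` and `arcs`.
#' @export
new_dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  } else {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2) stop("arcs must have two columns (from, to)")
    colnames(arcs) <- c("from", "to")
    storage.mode(arcs) <- "character"
  }
  bad <- setdiff(c(arcs), nodes)
  if (length(bad)) stop("arc endpoints not declared as nodes: ",
                        paste(unique(bad), collapse = ", "))
  if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
  key <- paste(arcs[, 1], arcs[, 2], sep = "\r")
  if (anyDuplicated(key)) arcs <- arcs[!duplicated(key), , drop = FALSE]
  d <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  topological_order(d)  # errors (naming a cycle) if cyclic
  d
}

# internal: logical adjacency matrix, amat[i, j] TRUE iff arc i -> j
dag_amat <- function(dag) {
  p <- length(dag$nodes)
  a <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs)) a[dag$arcs] <- TRUE
  a
}

# internal: rebuild a bn_dag from an adjacency matrix (assumed acyclic)
amat_to_dag <- function(amat) {
  idx <- which(amat, arr.ind = TRUE)
  nodes <- rownames(amat)
  arcs <- cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
  # deterministic arc order: by parent then child in canonical order
  if (nrow(arcs)) arcs <- arcs[order(idx[, 1], idx[, 2]), , drop = FALSE]
  structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with deterministic tie-breaking: among nodes whose
#' parents are all placed, the earliest in the declared node order is
#' emitted first, so an arc-free graph returns the canonical order.
#'
#' @param dag A [new_dag()] object (or a bare list with `nodes`/`arcs`).
#' @return Character vector: the nodes, every parent before its children.
#' @export
topological_order <- function(dag) {
  nodes <- dag$nodes
  amat <- {
    p <- length(nodes)
    a <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    if (NROW(dag$arcs)) a[as.matrix(dag$arcs[, 1:2, drop = FALSE])] <- TRUE
    a
  }
  indeg <- colSums(amat)
  out <- character(0)
  placed <- rep(FALSE, length(nodes))
  names(placed) <- nodes
  repeat {
    ready <- which(!placed & indeg == 0)
    if (!length(ready)) break
    nxt <- ready[1]  # smallest canonical index
    placed[nxt] <- TRUE
    out <- c(out, nodes[nxt])
    indeg <- indeg - amat[nxt, ]
  }
  if (length(out) < length(nodes)) {
    cyc <- find_cycle(amat, !placed)
    stop("graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  out
}

# internal: return one directed cycle among the given candidate nodes
find_cycle <- function(amat, candidate) {
  nodes <- rownames(amat)
  start <- which(candidate)[1]
  path <- integer(0)
  v <- start
  seen <- integer(0)
  repeat {
    path <- c(path, v)
    seen <- c(seen, v)
    nxt <- which(amat[v, ] & candidate)
    v <- nxt[1]
    if (v %in% path) {
      cyc <- path[which(path == v)[1]:length(path)]
      return(c(nodes[cyc], nodes[v]))
    }
  }
}

#' Parents of a node
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector of parent names (canonical order).
#' @export
parents_of <- function(dag, node) {
  sel <- dag$arcs[, 2] == node
  ps <- dag$arcs[sel, 1]
  dag$nodes[dag$nodes %in% ps]
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2]), sep = "\n")
  }
  invisible(x)
}

# internal: TRUE if a directed path from `from` to `to` exists in amat
has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(amat)
  visited <- rep(FALSE, p)
  frontier <- from
  visited[from] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(amat[v, ]))))
    nxt <- nxt[!visited[nxt]]
    if (to %in% nxt) return(TRUE)
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}
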