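# CPDAG (Markov equivalence class) utilities used to benchmark structure
# recovery: pattern extraction (skeleton + v-structures) closed under the
# Meek orientation rules, and the structural Hamming distance between two
# graphs compared as CPDAGs.

# internal pair codes: 0 none, 1 undirected, 2 i->j, 3 j->i (i < j)

# internal: p x p integer matrix M with M[i,j] = 1 if i->j directed,
# 2 if i-j undirected (stored symmetrically as 2), from a bn_dag
cpdag_amat <- function(dag) {
  nodes <- dag$nodes
  p <- length(nodes)
  dir_ <- dag_amat(dag)

  # pattern: skeleton everywhere undirected except v-structure colliders
  und <- dir_ | t(dir_)
  oriented <- matrix(FALSE, p, p, dimnames = dimnames(dir_))
  for (j in seq_len(p)) {
    pars <- which(dir_[, j])
    if (length(pars) < 2) next
    for (a in pars) for (b in pars) {
      if (a < b && !und[a, b]) {  # a -> j <- b with a,b nonadjacent
        oriented[a, j] <- TRUE
        oriented[b, j] <- TRUE
      }
    }
  }

  # Meek closure (rules 1-3 suffice when starting from a DAG's pattern)
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !und[a, b]) next
      if (oriented[a, b] || oriented[b, a]) next
      orient <- FALSE
      # R1: c -> a, c,b nonadjacent  =>  a -> b
      for (cc in which(oriented[, a])) {
        if (!und[cc, b] && cc != b) { orient <- TRUE; break }
      }
      # R2: a -> c -> b  =>  a -> b
      if (!orient) {
        for (cc in which(oriented[a, ])) {
          if (oriented[cc, b]) { orient <- TRUE; break }
        }
      }
      # R3: a - c -> b, a - d -> b, c,d nonadjacent  =>  a -> b
      if (!orient) {
        cand <- which(und[a, ] & !oriented[a, ] & !oriented[, a] & oriented[, b])
        cand <- setdiff(cand, c(a, b))
        if (length(cand) >= 2) {
          for (cc in cand) for (dd in cand) {
            if (cc < dd && !und[cc, dd]) { orient <- TRUE; break }
          }
        }
      }
      if (orient) {
        oriented[a, b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  out <- matrix(0L, p, p, dimnames = dimnames(dir_))
  out[oriented] <- 1L
  both <- und & !(oriented | t(oriented))
  out[both] <- 2L
  out
}

#' Completed partially directed acyclic graph of a DAG
#'
#' The canonical representative of the DAG's Markov equivalence class:
#' compelled arcs stay directed, reversible arcs become undirected lines.
#'
#' @param dag A [new_dag()].
#' @return Object of class `bn_cpdag` with `nodes`, a directed-arc matrix
#'   `arcs` and an undirected-edge matrix `edges`.
#' @export
cpdag <- function(dag) {
  m <- cpdag_amat(dag)
  nodes <- dag$nodes
  d_idx <- which(m == 1L, arr.ind = TRUE)
  u_idx <- which(m == 2L & upper.tri(m), arr.ind = TRUE)
  structure(list(
    nodes = nodes,
    arcs = cbind(from = nodes[d_idx[, 1]], to = nodes[d_idx[, 2]]),
    edges = cbind(a = nodes[u_idx[, 1]], b = nodes[u_idx[, 2]])
  ), class = "bn_cpdag")
}

#' @export
print.bn_cpdag <- function(x, ...) {
  cat("CPDAG:", nrow(x$arcs), "compelled arcs,", nrow(x$edges),
      "reversible edges\n")
  invisible(x)
}

#' Structural Hamming distance between two DAGs' equivalence classes
#'
#' Both DAGs are converted to CPDAGs; each unordered node pair whose
#' status differs (absent, undirected, or either direction) contributes 1.
#'
#' @param dag1,dag2 [new_dag()] objects over the same node set.
#' @return Non-negative integer.
#' @export
shd_cpdag <- function(dag1, dag2) {
  stopifnot(identical(dag1$nodes, dag2$nodes))
  m1 <- cpdag_amat(dag1)
  m2 <- cpdag_amat(dag2)
  p <- length(dag1$nodes)
  d <- 0L
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    t1 <- pair_type(m1, i, j)
    t2 <- pair_type(m2, i, j)
    if (t1 != t2) d <- d + 1L
  }
  d
}

pair_type <- function(m, i, j) {
  if (m[i, j] == 2L || m[j, i] == 2L) return(1L)
  if (m[i, j] == 1L) return(2L)
  if (m[j, i] == 1L) return(3L)
  0L
}

#' Skeleton precision/recall/F1 of a learned graph against the truth
#'
#' Compares undirected adjacencies only.
#'
#' @param learned,truth [new_dag()] objects over the same nodes.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
skeleton_f1 <- function(learned, truth) {
  und <- function(d) {
    a <- dag_amat(d); a <- a | t(a)
    which(a & upper.tri(a))
  }
  le <- und(learned); tr <- und(truth)
  tp <- length(intersect(le, tr))
  prec <- if (length(le)) tp / length(le) else 1
  rec <- if (length(tr)) tp / length(tr) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
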