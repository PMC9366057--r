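# Hybrid constraint/score structure learning in the H2PC family:
# Fisher-z partial-correlation tests drive a grow-shrink discovery of each
# node's candidate parents-children set; the AND-rule skeleton then
# restricts which arcs a BIC hill climb may add. Everything is
# deterministic given the canonical node order.

# internal: correlation-based sufficient statistics for CI testing
ci_stats <- function(data) {
  if (is.list(data) && !is.data.frame(data) && all(c("R", "n", "nodes") %in% names(data)))
    return(data)
  x <- as.matrix(data)
  sds <- apply(x, 2, stats::sd)
  R <- suppressWarnings(stats::cor(x))
  list(R = R, n = nrow(x), nodes = colnames(x), zero_var = colnames(x)[sds == 0])
}

# internal: partial correlation of x,y given cond from a correlation matrix
partial_cor <- function(R, x, y, cond) {
  if (!length(cond)) return(R[x, y])
  idx <- c(x, y, cond)
  Om <- tryCatch(solve(R[idx, idx]), error = function(e) NULL)
  if (is.null(Om)) {
    # fall back on a pseudo-inverse for (near-)singular conditioning sets
    s <- svd(R[idx, idx])
    pos <- s$d > max(s$d) * 1e-12
    Om <- s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

#' Fisher-z test of (partial) correlation
#'
#' Tests independence of `x` and `y` given a conditioning set under the
#' Gaussian model: the partial correlation r is mapped through
#' z = atanh(r) * sqrt(n - |cond| - 3) and referred to the standard
#' normal (two-sided).
#'
#' @param data Numeric matrix (rows = observations) or a cached internal
#'   statistics object.
#' @param x,y Column names to test; must differ and not appear in `cond`.
#' @param cond Character vector of conditioning columns (possibly empty).
#' @return List of class `ci_test` with `partial_r`, `z_stat`, `p_value`,
#'   `conditioning_size` and a logical `saturated` flag set when |r| is
#'   numerically 1 (p is then exactly 0).
#' @export
fisher_z_test <- function(data, x, y, cond = character(0)) {
  st <- ci_stats(data)
  if (x == y) stop("x and y must differ")
  if (x %in% cond || y %in% cond) stop("x and y must not be in the conditioning set")
  df <- st$n - length(cond) - 3
  if (df <= 0)
    stop("insufficient sample size: need n - |cond| - 3 > 0 (n = ", st$n,
         ", |cond| = ", length(cond), ")")
  r <- partial_cor(st$R, x, y, cond)
  r <- max(min(r, 1), -1)
  saturated <- abs(r) >= 1 - 1e-12
  if (saturated) {
    z <- sign(r) * Inf
    p <- 0
  } else {
    z <- atanh(r) * sqrt(df)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(partial_r = r, z_stat = z, p_value = p,
                 conditioning_size = length(cond), saturated = saturated),
            class = "ci_test")
}

# internal: all subsets of v with size 0..k, smallest first, lexicographic
subsets_up_to <- function(v, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(v)))) {
    cmb <- utils::combn(v, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Candidate parents-children set of one node
#'
#' Grow-shrink discovery with Fisher-z tests: grow by repeatedly admitting
#' the candidate with the smallest p-value below `alpha` given the current
#' set; then prune any member that some subset (size <= `max_sepset`) of
#' the remaining members renders independent of the target. Candidates are
#' always scanned in canonical column order, so the result is
#' deterministic.
#'
#' @param data Data matrix or cached statistics.
#' @param target Node name.
#' @param alpha Significance level in (0, 1).
#' @param max_sepset Largest conditioning-subset size tried while pruning.
#' @return Character vector of neighbor names (canonical order).
#' @export
discover_neighbors <- function(data, target, alpha = 0.05, max_sepset = 3) {
  st <- ci_stats(data)
  stopifnot(alpha > 0, alpha < 1)
  others <- setdiff(st$nodes, target)
  if (!length(others)) return(character(0))
  cpc <- character(0)
  # grow
  repeat {
    cands <- setdiff(others, cpc)
    if (!length(cands)) break
    if (st$n - length(cpc) - 3 <= 0) break   # cannot test any further
    pv <- vapply(cands, function(v)
      fisher_z_test(st, target, v, cpc)$p_value, numeric(1))
    best <- which.min(pv)                    # first minimum = canonical order
    if (pv[best] >= alpha) break
    cpc <- others[others %in% c(cpc, cands[best])]
  }
  # shrink
  repeat {
    removed <- FALSE
    for (v in cpc) {
      rest <- setdiff(cpc, v)
      feasible <- min(max_sepset, length(rest), st$n - 4)
      for (ss in subsets_up_to(rest, max(feasible, 0))) {
        if (st$n - length(ss) - 3 <= 0) next
        if (fisher_z_test(st, target, v, ss)$p_value >= alpha) {
          cpc <- setdiff(cpc, v)
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }
  st$nodes[st$nodes %in% cpc]
}

#' Undirected skeleton by symmetric neighbor discovery
#'
#' Runs [discover_neighbors()] for every node and keeps edge \{x, y\} only
#' when each node is in the other's neighbor set (AND rule).
#'
#' @inheritParams discover_neighbors
#' @return Object of class `bn_skeleton`: `nodes` and a two-column matrix
#'   `edges` of unordered pairs (first endpoint earlier in canonical
#'   order).
#' @export
build_skeleton <- function(data, alpha = 0.05, max_sepset = 3) {
  st <- ci_stats(data)
  nb <- lapply(st$nodes, function(v) discover_neighbors(st, v, alpha, max_sepset))
  names(nb) <- st$nodes
  edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  p <- length(st$nodes)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      a <- st$nodes[i]; b <- st$nodes[j]
      if (b %in% nb[[a]] && a %in% nb[[b]]) edges <- rbind(edges, c(a, b))
    }
  }
  structure(list(nodes = st$nodes, edges = edges), class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat("Skeleton with", length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  invisible(x)
}

# internal: symmetric logical allowed-adjacency matrix from a skeleton
skeleton_mask <- function(skeleton, nodes) {
  p <- length(nodes)
  m <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(skeleton)) {
    m[] <- FALSE
    e <- skeleton$edges
    if (nrow(e)) {
      m[e] <- TRUE
      m[e[, c(2, 1), drop = FALSE]] <- TRUE
    }
  }
  diag(m) <- FALSE
  m
}

#' Greedy BIC hill climbing over DAGs
#'
#' Starts from the empty graph and repeatedly applies the single best
#' strictly score-improving move among arc additions, deletions and
#' reversals, stopping at a local optimum or after `max_iter` moves.
#' Additions are restricted to pairs adjacent in `constraint` (either
#' orientation) when one is supplied; deletions and reversals are always
#' allowed. Ties are broken by scanning moves in a fixed order
#' (add, delete, reverse; then parent, then child in canonical order).
#'
#' Because BIC is score-equivalent, a local optimum can sit on a plateau
#' of Markov-equivalent DAGs (score-neutral arc reversals) from which a
#' strictly better move is reachable; the search deterministically
#' traverses such plateaus (breadth-first over neutral reversals, visited
#' states memoized, bounded by `plateau_cap`) before declaring
#' convergence.
#'
#' @param data Data matrix or [moment_stats()].
#' @param constraint Optional [build_skeleton()] result restricting
#'   additions.
#' @param max_iter Maximum number of accepted strictly-improving moves.
#' @param plateau_cap Maximum number of equivalent states explored per
#'   plateau.
#' @return A [new_dag()] at the (plateau-closed) local optimum.
#' @export
hill_climb <- function(data, constraint = NULL, max_iter = 200L,
                       plateau_cap = 200L) {
  stats <- as_moment_stats(data)
  nodes <- stats$nodes
  p <- length(nodes)
  cache <- new_score_cache()
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  allowed <- skeleton_mask(constraint, nodes)
  local <- vapply(nodes, function(v) local_bic(stats, v, character(0), cache),
                  numeric(1))
  eps <- 1e-10
  score_family <- function(j, ps) local_bic(stats, nodes[j], ps, cache)
  pa_names <- function(a, j) nodes[a[, j]]

  # best strictly-improving move from state `a` (with local scores `loc`),
  # scanned in the deterministic (operation, parent, child) order
  best_strict <- function(a, loc) {
    best_delta <- eps
    best_move <- NULL
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || a[i, j] || a[j, i] || !allowed[i, j]) next
      if (has_path(a, j, i)) next  # would create a cycle
      d <- score_family(j, c(pa_names(a, j), nodes[i])) - loc[j]
      if (d > best_delta) { best_delta <- d; best_move <- list("add", i, j) }
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!a[i, j]) next
      d <- score_family(j, setdiff(pa_names(a, j), nodes[i])) - loc[j]
      if (d > best_delta) { best_delta <- d; best_move <- list("delete", i, j) }
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!a[i, j]) next
      a[i, j] <- FALSE
      cyc <- has_path(a, i, j)
      a[i, j] <- TRUE
      if (cyc) next
      d <- (score_family(i, c(pa_names(a, i), nodes[j])) - loc[i]) +
           (score_family(j, setdiff(pa_names(a, j), nodes[i])) - loc[j])
      if (d > best_delta) { best_delta <- d; best_move <- list("reverse", i, j) }
    }
    best_move
  }

  apply_move <- function(a, loc, move) {
    op <- move[[1]]; i <- move[[2]]; j <- move[[3]]
    if (op == "add") {
      a[i, j] <- TRUE
      loc[j] <- score_family(j, pa_names(a, j))
    } else if (op == "delete") {
      a[i, j] <- FALSE
      loc[j] <- score_family(j, pa_names(a, j))
    } else {
      a[i, j] <- FALSE
      a[j, i] <- TRUE
      loc[i] <- score_family(i, pa_names(a, i))
      loc[j] <- score_family(j, pa_names(a, j))
    }
    list(amat = a, local = loc)
  }

  # breadth-first over score-neutral reversals from a local optimum;
  # returns a state holding a strictly-improving move, or NULL
  escape_plateau <- function(a, loc) {
    key <- function(m) paste0("k", paste(which(m), collapse = ","))
    queue <- list(list(amat = a, local = loc))
    visited <- new.env(parent = emptyenv())
    assign(key(a), TRUE, envir = visited)
    n_seen <- 1L
    while (length(queue)) {
      st <- queue[[1]]
      queue <- queue[-1]
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (!st$amat[i, j]) next
        a2 <- st$amat
        a2[i, j] <- FALSE
        if (has_path(a2, i, j)) next
        d <- (score_family(i, c(pa_names(a2, i), nodes[j])) - st$local[i]) +
             (score_family(j, setdiff(pa_names(a2, j), nodes[i])) - st$local[j])
        if (abs(d) > eps) next          # neutral reversals only
        nxt <- apply_move(st$amat, st$local, list("reverse", i, j))
        k <- key(nxt$amat)
        if (!is.null(visited[[k]])) next
        assign(k, TRUE, envir = visited)
        if (!is.null(best_strict(nxt$amat, nxt$local))) return(nxt)
        n_seen <- n_seen + 1L
        if (n_seen >= plateau_cap) return(NULL)
        queue[[length(queue) + 1L]] <- nxt
      }
    }
    NULL
  }

  iter <- 0L
  while (iter < max_iter) {
    move <- best_strict(amat, local)
    if (is.null(move)) {
      esc <- escape_plateau(amat, local)
      if (is.null(esc)) break
      amat <- esc$amat
      local <- esc$local
      move <- best_strict(amat, local)
    }
    st <- apply_move(amat, local, move)
    amat <- st$amat
    local <- st$local
    iter <- iter + 1L
  }
  amat_to_dag(amat)
}

#' Hybrid structure learning (skeleton, then restricted search)
#'
#' [build_skeleton()] followed by [hill_climb()] constrained to the
#' skeleton. Every arc of the result joins a skeleton-adjacent pair.
#'
#' @inheritParams build_skeleton
#' @param max_iter Passed to [hill_climb()].
#' @return A [new_dag()].
#' @export
learn_structure <- function(data, alpha = 0.05, max_sepset = 3, max_iter = 200L) {
  x <- as.matrix(data)
  skel <- build_skeleton(x, alpha = alpha, max_sepset = max_sepset)
  hill_climb(moment_stats(x), constraint = skel, max_iter = max_iter)
}
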