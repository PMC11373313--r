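#' Approximate compatibility of two cluster records
#'
#' On multilabeled trees the set compatibility rule fails, so cluster
#' selection relies on a relaxed multiset relation: records (C1, m1) and
#' (C2, m2) drawn from a target leaf multiset L are approximately compatible
#' if C1 is a sub-multiset of C2, or C2 of C1, or removing m1 copies of C1
#' from L leaves room for m2 copies of C2 (multiset subtraction floored at
#' zero). As printed, the third condition is directional; by default it is
#' evaluated in both directions so the relation is symmetric, as an
#' undirected compatibility graph requires (`symmetric = FALSE` gives the
#' literal one-directional reading).
#'
#' @param r1,r2 records with `$cluster` and `$multiplicity`.
#' @param L the target `label_multiset`.
#' @param symmetric evaluate the removal condition in both directions.
#' @return Logical.
#' @export
approx_compatible <- function(r1, r2, L, symmetric = TRUE) {
  if (!ms_contains(L, r1$cluster) || !ms_contains(L, r2$cluster))
    stop("cluster not contained in target multiset L")
  if (ms_contains(r2$cluster, r1$cluster)) return(TRUE)
  if (ms_contains(r1$cluster, r2$cluster)) return(TRUE)
  third <- function(a, b) {
    ms_contains(ms_diff(L, ms_scale(a$cluster, a$multiplicity)),
                ms_scale(b$cluster, b$multiplicity))
  }
  if (third(r1, r2)) return(TRUE)
  if (symmetric && third(r2, r1)) return(TRUE)
  FALSE
}

#' Node weight of a cluster record
#'
#' w = m * s * |C|^alpha, where m is the within-tree multiplicity, s the
#' cross-tree frequency and |C| the multiset size of the cluster. The
#' exponent (default 0.65) damps the influence of cluster size relative to
#' multiplicity and frequency.
#'
#' @param record a record with `$cluster`, `$multiplicity`, `$frequency`.
#' @param alpha positive size exponent.
#' @return Positive numeric weight.
#' @examples
#' node_weight(list(cluster = label_multiset(c("a", "b", "c")),
#'                  multiplicity = 2L, frequency = 5L))  # ~20.41
#' @export
node_weight <- function(record, alpha = 0.65) {
  stopifnot(alpha > 0)
  record$multiplicity * record$frequency * ms_size(record$cluster)^alpha
}

#' Build the approximate compatibility graph
#'
#' One weighted vertex per cluster record; an undirected edge joins every
#' approximately compatible pair. Records whose cluster does not fit inside
#' L at their multiplicity are dropped with a warning. Vertices sharing a
#' base cluster (same multiset, different multiplicity) are grouped: any
#' feasible selection takes at most one per group.
#'
#' @param records sorted record list from [compute_sorted_clusters()].
#' @param L the target `label_multiset`.
#' @param alpha size exponent for [node_weight()].
#' @param symmetric passed to [approx_compatible()].
#' @return A `compat_graph`: list with `records`, `weight`, `adj` (logical
#'   matrix), `group` (integer vector).
#' @export
build_graph <- function(records, L, alpha = 0.65, symmetric = TRUE) {
  fits <- vapply(records, function(r)
    ms_contains(L, ms_scale(r$cluster, r$multiplicity)), logical(1))
  if (any(!fits))
    warning(sum(!fits), " record(s) do not fit in L at their multiplicity;",
            " dropped")
  records <- records[fits]
  n <- length(records)
  w <- vapply(records, node_weight, numeric(1), alpha = alpha)
  keys <- vapply(records, function(r) ms_key(r$cluster), character(1))
  group <- match(keys, unique(keys))
  adj <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ok <- approx_compatible(records[[i]], records[[j]], L,
                                symmetric = symmetric)
        adj[i, j] <- ok
        adj[j, i] <- ok
      }
    }
  }
  structure(list(records = records, weight = w, adj = adj, group = group,
                 L = L),
            class = "compat_graph")
}

#' Solve the maximum-weight approximately-compatible cluster problem
#'
#' Selects a maximum-weight subset of vertices that is pairwise adjacent in
#' the compatibility graph with at most one multiplicity per base cluster --
#' a maximum-weight clique once same-cluster vertices are made mutually
#' exclusive. `solve_mwacc()` is an exact branch-and-bound (vertices in
#' descending weight order, residual-weight bound); no MILP solver is
#' assumed. `solve_mwacc_bruteforce()` exhaustively enumerates all subsets
#' (<= 20 vertices) and serves as the independent validation oracle; ties
#' resolve to the lexicographically smallest vertex index set.
#'
#' @param graph a `compat_graph`.
#' @param max_nodes search-node budget; exceeding it is an error (the
#'   solver is exact or fails loudly, never silently approximate).
#' @return List with `selected` (integer vertex ids, increasing) and
#'   `total_weight`.
#' @export
solve_mwacc <- function(graph, max_nodes = 1e7) {
  n <- length(graph$weight)
  if (n == 0L) return(list(selected = integer(0), total_weight = 0))
  eff <- graph$adj & outer(graph$group, graph$group, "!=")
  ord <- order(-graph$weight, seq_len(n), method = "radix")
  w <- graph$weight[ord]
  A <- eff[ord, ord, drop = FALSE]
  suffix <- rev(cumsum(rev(w)))
  best_w <- -Inf; best_sel <- integer(0)
  nodes <- 0L
  expand <- function(sel, cur_w, cand) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes)
      stop("solve_mwacc: search budget exceeded (", max_nodes, " nodes)")
    if (cur_w > best_w + 1e-12) {
      best_w <<- cur_w
      best_sel <<- sel
    }
    for (k in seq_along(cand)) {
      v <- cand[k]
      # cand is in descending-weight order, so suffix[v] bounds what remains
      if (cur_w + suffix[v] <= best_w + 1e-12) break
      rest <- cand[-seq_len(k)]
      expand(c(sel, v), cur_w + w[v], rest[A[v, rest]])
    }
  }
  expand(integer(0), 0, seq_len(n))
  list(selected = sort(ord[best_sel]), total_weight = best_w)
}

#' @rdname solve_mwacc
#' @export
solve_mwacc_bruteforce <- function(graph) {
  n <- length(graph$weight)
  if (n > 20L) stop("brute force capped at 20 vertices")
  if (n == 0L) return(list(selected = integer(0), total_weight = 0))
  eff <- graph$adj & outer(graph$group, graph$group, "!=")
  best_w <- 0; best_sel <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(sel) >= 2L) {
      ok <- TRUE
      for (i in seq_len(length(sel) - 1L)) {
        if (!all(eff[sel[i], sel[(i + 1L):length(sel)]])) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    tw <- sum(graph$weight[sel])
    if (tw > best_w + 1e-9) {
      best_w <- tw; best_sel <- sel
    } else if (abs(tw - best_w) <= 1e-9 && length(best_sel) > 0L &&
               lex_less(sel, best_sel)) {
      best_sel <- sel
    }
  }
  list(selected = best_sel, total_weight = best_w)
}

# lexicographic order on integer index sets
lex_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}

#' Post-hoc validity check of an MWACC selection
#'
#' Recomputes, independently of any solver, that a selection is pairwise
#' approximately compatible and takes at most one multiplicity per base
#' cluster.
#'
#' @param graph a `compat_graph`.
#' @param solution list with `selected`.
#' @return Logical.
#' @export
mwacc_solution_valid <- function(graph, solution) {
  sel <- solution$selected
  if (length(sel) < 2L) return(TRUE)
  if (anyDuplicated(graph$group[sel]) > 0L) return(FALSE)
  for (i in seq_len(length(sel) - 1L)) {
    for (j in seq(i + 1L, length(sel))) {
      if (!approx_compatible(graph$records[[sel[i]]],
                             graph$records[[sel[j]]], graph$L))
        return(FALSE)
    }
  }
  TRUE
}
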