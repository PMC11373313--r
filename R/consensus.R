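#' Start a growing consensus as a star tree
#'
#' Creates the star tree on the target multiset L: a root with one leaf
#' child per element of L counted with multiplicity (the distinguishable
#' leaf copies are the "instances" the insertion search assigns clusters
#' to; instance identity is an internal device, erased before output).
#'
#' @param L a `label_multiset`.
#' @return A `growing_consensus` environment.
#' @export
build_star <- function(L) {
  stopifnot(ms_size(L) >= 1L)
  labs <- rep(names(L), ms_strip(L))
  n <- length(labs)
  st <- new.env(parent = emptyenv())
  st$parent <- c(NA_integer_, rep(1L, n))
  st$children <- c(list(seq_len(n) + 1L), rep(list(integer(0)), n))
  st$label <- c(NA_character_, labs)
  st$root <- 1L
  st$accepted <- list()
  class(st) <- "growing_consensus"
  st
}

gc_as_multree <- function(st) {
  multree(st$parent, st$children, st$label, root = st$root)
}

#' @export
print.growing_consensus <- function(x, ...) {
  cat("<growing_consensus> ", write_newick(gc_as_multree(x)), "\n", sep = "")
  invisible(x)
}

# leaf ids below every node of the growing tree
gc_leafsets <- function(st) {
  n <- length(st$parent)
  out <- vector("list", n)
  tr <- list(parent = st$parent, children = st$children, label = st$label,
             root = st$root)
  class(tr) <- "multree"
  for (v in postorder(tr)) {
    ch <- st$children[[v]]
    out[[v]] <- if (length(ch) == 0L) v else
      sort(unlist(out[ch], use.names = FALSE))
  }
  out
}

# ordered candidate realizations of cluster C on the current tree: either
# an existing clade whose cluster equals C, or a grouping of >= 2 complete
# child subtrees of one node whose label multisets sum to C (any such
# grouping is automatically set-compatible with every clade already in the
# tree). Deepest attachment point first, so insertions reinforce existing
# structure; ties break by node id and child position.
gc_candidates <- function(state, C) {
  tr <- gc_as_multree(state)
  leafsets <- gc_leafsets(state)
  clmap <- node_clusters(tr)
  depths <- node_depths(tr)
  csize <- ms_size(C)
  cands <- list()
  add_cand <- function(leafset, new_group, depth, ord1, ord2) {
    cands[[length(cands) + 1L]] <<- list(leafset = leafset, new = new_group,
                                         depth = depth, o1 = ord1, o2 = ord2)
  }
  for (v in seq_along(state$parent)) {
    if (ms_equal(clmap[[v]], C))
      add_cand(leafsets[[v]], NULL, depths[v], v, 0L)
  }
  for (u in which(lengths(state$children) > 1L)) {
    ch <- state$children[[u]]
    d <- length(ch)
    sizes <- vapply(ch, function(c) ms_size(clmap[[c]]), integer(1))
    rec_sub <- function(i, chosen, acc) {
      got <- ms_size(acc)
      if (got == csize) {
        if (length(chosen) >= 2L && length(chosen) < d) {
          if (ms_equal(acc, C))
            add_cand(sort(unlist(leafsets[ch[chosen]], use.names = FALSE)),
                     list(u = u, members = ch[chosen]),
                     depths[u], u, chosen[1])
        }
        return()
      }
      if (i > d || got > csize) return()
      if (got + sum(sizes[i:d]) < csize) return()
      cand_acc <- ms_sum(acc, clmap[[ch[i]]])
      if (ms_contains(C, cand_acc))
        rec_sub(i + 1L, c(chosen, i), cand_acc)
      rec_sub(i + 1L, chosen, acc)
    }
    rec_sub(1L, integer(0), label_multiset(character(0)))
  }
  ord <- order(-vapply(cands, `[[`, integer(1), "depth"),
               vapply(cands, `[[`, numeric(1), "o1"),
               vapply(cands, `[[`, numeric(1), "o2"))
  cands[ord]
}

# apply the new groupings of a chosen combo; returns undo information
gc_apply <- function(state, combo) {
  undo <- list(n = length(state$parent), touched = list())
  for (cand in combo) {
    grp <- cand$new
    if (is.null(grp)) next                 # existing clade reused
    u <- grp$u
    members <- grp$members
    undo$touched[[length(undo$touched) + 1L]] <-
      list(u = u, children = state$children[[u]], members = members)
    id <- length(state$parent) + 1L
    state$parent[id] <- u
    state$children[[id]] <- members
    state$label[id] <- NA_character_
    for (c in members) state$parent[c] <- id
    ch <- state$children[[u]]
    pos <- match(members[1], ch)
    ch <- ch[!(ch %in% members)]
    state$children[[u]] <- append(ch, id, after = pos - 1L)
  }
  undo
}

gc_undo <- function(state, undo) {
  for (t in rev(undo$touched)) {
    state$children[[t$u]] <- t$children
    for (c in t$members) state$parent[c] <- t$u
  }
  n <- undo$n
  length(state$parent) <- n
  length(state$children) <- n
  length(state$label) <- n
  invisible(state)
}

# depth-first search realizing records[i..] on the mutable state; combos
# for one record are the ordered selections of m pairwise-disjoint
# candidates. `counter` is an environment with `left` (search budget).
gc_dfs_records <- function(state, records, i, counter) {
  if (i > length(records)) return(TRUE)
  C <- records[[i]]$cluster
  m <- records[[i]]$multiplicity
  # candidate generation is the costly step: charge it 10 budget units
  counter$left <- counter$left - 10L
  if (counter$left < 0L) stop(condition_budget())
  cands <- gc_candidates(state, C)
  if (length(cands) < m) return(FALSE)
  pick <- function(start, chosen) {
    if (length(chosen) == m) {
      counter$left <- counter$left - 1L
      if (counter$left < 0L) stop(condition_budget())
      undo <- gc_apply(state, cands[chosen])
      if (gc_dfs_records(state, records, i + 1L, counter)) return(TRUE)
      gc_undo(state, undo)
      return(FALSE)
    }
    if (start > length(cands)) return(FALSE)
    for (k in start:length(cands)) {
      if (length(cands) - k + 1L < m - length(chosen)) break
      ls <- cands[[k]]$leafset
      disjoint <- all(vapply(chosen, function(p)
        length(intersect(cands[[p]]$leafset, ls)) == 0L, logical(1)))
      if (!disjoint) next
      if (pick(k + 1L, c(chosen, k))) return(TRUE)
    }
    FALSE
  }
  pick(1L, integer(0))
}

condition_budget <- function() {
  structure(class = c("mulfold_budget", "condition"),
            list(message = "insertion budget exhausted", call = NULL))
}

#' Try to insert a cluster-multiplicity record into the consensus
#'
#' Searches for m pairwise-disjoint realizations of cluster C among the
#' leaf instances of the growing tree: each realization is an existing
#' clade whose cluster equals C or a grouping of two or more complete
#' child subtrees of one node summing to C (automatically set-compatible
#' with every clade already in the tree). Candidates are tried deepest
#' attachment point first; the backtracking search counts combo
#' applications against `budget`, and exhaustion counts as failure. On
#' success the state is mutated (new internal nodes added) and `TRUE`
#' returned; otherwise the state is untouched and `FALSE` returned.
#'
#' @param state a `growing_consensus`.
#' @param record list with `$cluster` and `$multiplicity`.
#' @param budget backtracking budget.
#' @return Logical: was the cluster realized?
#' @export
try_insert_cluster <- function(state, record, budget = 1e5) {
  counter <- new.env(parent = emptyenv())
  counter$left <- budget
  snap <- list(parent = state$parent, children = state$children,
               label = state$label)
  ok <- tryCatch(
    gc_dfs_records(state, list(record), 1L, counter),
    mulfold_budget = function(c) {
      message("insertion budget exhausted for cluster {",
              ms_key(record$cluster, ","), "} x", record$multiplicity,
              "; treated as incompatible")
      NA
    })
  if (is.na(ok)) {                 # search aborted mid-flight: roll back
    state$parent <- snap$parent
    state$children <- snap$children
    state$label <- snap$label
    return(FALSE)
  }
  if (ok)
    state$accepted[[length(state$accepted) + 1L]] <- record
  ok
}

## ---------------------------------------------------------------- refine --

# map from base-cluster key to the best (max) node weight among records
weight_lookup <- function(records, alpha) {
  env <- new.env(parent = emptyenv())
  for (r in records) {
    k <- ms_key(r$cluster)
    w <- node_weight(r, alpha)
    if (is.null(env[[k]]) || w > env[[k]]) env[[k]] <- w
  }
  function(cluster) {
    v <- env[[ms_key(cluster)]]
    if (is.null(v)) 0 else v
  }
}

# exact maximum-weight binary resolution of child groups by subset DP
refine_dp <- function(group_clusters, wfun) {
  d <- length(group_clusters)
  nmask <- bitwShiftL(1L, d)
  cl <- vector("list", nmask)            # cluster multiset per subset
  best <- numeric(nmask)
  split <- integer(nmask)                # chosen first part (mask), 0 = leaf
  singles <- bitwShiftL(1L, seq_len(d) - 1L)
  for (mask in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(mask, singles) != 0L)
    if (length(members) == 1L) {
      cl[[mask + 1L]] <- group_clusters[[members]]
      best[mask + 1L] <- 0
      next
    }
    lowest <- singles[members[1]]
    acc <- Reduce(ms_sum, group_clusters[members])
    cl[[mask + 1L]] <- acc
    w_here <- wfun(acc)
    b <- -Inf; bs <- 0L
    # splits A | mask\A with A containing the lowest member, ascending so
    # that under all-zero weights the first (caterpillar) split is kept
    rest <- bitwAnd(mask, bitwNot(lowest))
    sub <- 0L
    repeat {
      A <- bitwOr(sub, lowest)
      B <- bitwAnd(mask, bitwNot(A))
      if (B != 0L) {
        v <- best[A + 1L] + best[B + 1L]
        if (v > b + 1e-12) { b <- v; bs <- A }
      }
      if (sub == rest) break
      sub <- bitwAnd(sub - rest, rest)
    }
    best[mask + 1L] <- w_here + b
    split[mask + 1L] <- bs
  }
  list(best = best, split = split, singles = singles)
}

#' Refine a multifurcating node to a binary subtree
#'
#' Regroups the children of an unresolved node into a binary subtree
#' maximizing the total weight of the newly induced clusters: a grouping
#' scores the node weight of the best matching record for its induced
#' cluster, 0 if unseen. For out-degree up to `exhaustive_cap` (default 6)
#' the optimum over all rooted binary shapes is found exactly (subset DP);
#' beyond that, greedy agglomeration repeatedly merges the pair with the
#' heaviest union, ties to the lexicographically smallest union. With
#' all-zero weights the result is the deterministic left-to-right
#' caterpillar.
#'
#' @param tree a `multree`.
#' @param v id of a node with out-degree >= 3.
#' @param records cluster record list consulted for weights (the full
#'   filtered census, not only the selected subset).
#' @param alpha size exponent.
#' @param exhaustive_cap largest out-degree resolved exactly.
#' @return The modified `multree`.
#' @export
refine_node <- function(tree, v, records, alpha = 0.65, exhaustive_cap = 6L) {
  ch <- tree$children[[v]]
  d <- length(ch)
  if (d < 3L) return(tree)
  clmap <- node_clusters(tree)
  wfun <- weight_lookup(records, alpha)
  # mutable accumulators over tree vectors
  parent <- tree$parent; children <- tree$children
  label <- tree$label; len <- tree$length
  new_internal <- function(kids) {
    id <- length(parent) + 1L
    parent[id] <<- NA_integer_
    children[[id]] <<- kids
    label[id] <<- NA_character_
    len[id] <<- NA_real_
    for (k in kids) parent[k] <<- id
    id
  }
  if (d <= exhaustive_cap) {
    dp <- refine_dp(clmap[ch], wfun)
    build <- function(mask) {
      members <- which(bitwAnd(mask, dp$singles) != 0L)
      if (length(members) == 1L) return(ch[members])
      A <- dp$split[mask + 1L]
      B <- bitwAnd(mask, bitwNot(A))
      new_internal(c(build(A), build(B)))
    }
    full <- bitwShiftL(1L, d) - 1L
    A <- dp$split[full + 1L]
    B <- bitwAnd(full, bitwNot(A))
    kids <- c(build(A), build(B))
  } else {
    groups <- as.list(ch)
    gcl <- clmap[ch]
    while (length(groups) > 2L) {
      bw <- -Inf; bk <- NULL; bkey <- ""
      for (i in seq_len(length(groups) - 1L)) {
        for (j in seq(i + 1L, length(groups))) {
          un <- ms_sum(gcl[[i]], gcl[[j]])
          wv <- wfun(un)
          key <- ms_key(un)
          if (wv > bw + 1e-12 ||
              (abs(wv - bw) <= 1e-12 && key < bkey)) {
            bw <- wv; bk <- c(i, j); bkey <- key
          }
        }
      }
      i <- bk[1]; j <- bk[2]
      id <- new_internal(c(groups[[i]], groups[[j]]))
      groups[[i]] <- id
      gcl[[i]] <- ms_sum(gcl[[i]], gcl[[j]])
      groups[[j]] <- NULL
      gcl[[j]] <- NULL
    }
    kids <- unlist(groups)
  }
  children[[v]] <- kids
  for (k in kids) parent[k] <- v
  multree(parent, children, label, len, root = tree$root)
}

## -------------------------------------------------------------- pipeline --

# target multiset default: per-label maximum multiplicity over gene trees
infer_target_multiset <- function(gene_trees) {
  env <- new.env(parent = emptyenv())
  for (tr in gene_trees) {
    ms <- leaf_multiset(tr)
    for (lab in names(ms)) {
      cur <- if (is.null(env[[lab]])) 0L else env[[lab]]
      env[[lab]] <- max(cur, ms_strip(ms)[[lab]])
    }
  }
  labs <- ls(env, sorted = TRUE)
  label_multiset(stats::setNames(vapply(labs, function(l) env[[l]],
                                        integer(1)), labs))
}

#' Build the consensus MUL-tree from gene trees
#'
#' The full MUL-tree reconstruction pipeline: census the gene-tree clusters
#' with exact-multiplicity frequencies, filter by minimum frequency `tau`,
#' build the approximate compatibility graph, select a maximum-weight
#' approximately compatible subset exactly, greedily insert the selected
#' clusters in descending frequency order into a star tree on L, and
#' finally refine every remaining multifurcation by maximum-weight binary
#' resolution (consulting the full filtered census, not only the selected
#' subset).
#'
#' @param gene_trees non-empty list of `multree` objects.
#' @param L target `label_multiset`; default: per-label maximum
#'   multiplicity observed across the gene trees.
#' @param alpha cluster-size exponent (default 0.65).
#' @param tau minimum cluster frequency (default 1 = no filtering).
#' @param refine resolve multifurcations to binary (default TRUE).
#' @param exhaustive_cap largest out-degree refined exactly.
#' @param budget backtracking budget per cluster insertion.
#' @return List with `tree` (the consensus `multree`), `map` (cluster
#'   frequency map), `records` (filtered census), `selected` (indices into
#'   `records` chosen by the solver), `objective` (solver total weight).
#' @export
build_consensus <- function(gene_trees, L = NULL, alpha = 0.65, tau = 1L,
                            refine = TRUE, exhaustive_cap = 6L,
                            budget = 1e5) {
  if (is.null(L)) L <- infer_target_multiset(gene_trees)
  sc <- compute_sorted_clusters(gene_trees)
  recs <- filter_by_frequency(sc$records, tau)
  graph <- build_graph(recs, L, alpha = alpha)
  sol <- solve_mwacc(graph)
  # insertion order: frequency-major as in the sorted census, but
  # size-ascending within equal frequency (bottom-up realization: every
  # cluster's constituent subtrees exist before the cluster arrives, which
  # a size-descending pass does not guarantee on multilabeled input)
  sel <- graph$records[sol$selected]
  ordins <- order(-vapply(sel, `[[`, integer(1), "frequency"),
                  vapply(sel, function(r) ms_size(r$cluster), integer(1)),
                  vapply(sel, function(r) ms_key(r$cluster), character(1)),
                  method = "radix")
  # chronological backtracking across records: a new record may force a
  # different realization of earlier ones, but never their removal, so the
  # greedy priority order is preserved; exhaustion skips the new record
  realized <- list()
  good <- build_star(L)
  for (r in sel[ordins]) {
    trial <- build_star(L)
    counter <- new.env(parent = emptyenv())
    counter$left <- budget
    ok <- tryCatch(
      gc_dfs_records(trial, c(realized, list(r)), 1L, counter),
      mulfold_budget = function(c) {
        message("insertion budget exhausted for cluster {",
                ms_key(r$cluster, ","), "} x", r$multiplicity,
                "; treated as incompatible")
        FALSE
      })
    if (ok) {
      realized <- c(realized, list(r))
      good <- trial
    }
  }
  good$accepted <- realized
  tree <- gc_as_multree(good)
  if (refine) {
    repeat {
      deg <- lengths(tree$children)
      multi <- which(deg >= 3L)
      if (length(multi) == 0L) break
      tree <- refine_node(tree, multi[1], recs, alpha = alpha,
                          exhaustive_cap = exhaustive_cap)
    }
  }
  list(tree = tree, map = sc$map, records = recs,
       selected = sol$selected, accepted = good$accepted,
       objective = sol$total_weight)
}
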