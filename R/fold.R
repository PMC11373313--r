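#' Near-isomorphism test between two clades of one tree
#'
#' Two clades are candidates for merging into a reticulation only if they
#' induce exactly the same cluster multiset (copy numbers included). Given
#' equal clusters, they are near-isomorphic if their canonical codes match
#' (exact isomorphism) or their normalized tree edit distance is at most
#' `delta`. With `delta = 0` only exactly isomorphic clades merge -- the
#' classical folding procedure.
#'
#' @param tree a `multree`.
#' @param u,v node ids.
#' @param delta threshold in [0, 1].
#' @param codes optional precomputed [assign_codes()] vector.
#' @param clusters optional precomputed cluster list.
#' @return Logical.
#' @export
are_near_isomorphic <- function(tree, u, v, delta, codes = NULL,
                                clusters = NULL) {
  if (is.null(codes)) codes <- assign_codes(tree)
  if (is.null(clusters)) clusters <- node_clusters(tree)
  if (!ms_equal(clusters[[u]], clusters[[v]])) return(FALSE)
  if (identical(codes[u], codes[v])) return(TRUE)
  normalized_ged(subtree(tree, u), subtree(tree, v)) <= delta
}

#' Gene-tree support score of a clade
#'
#' Sums, over every cluster-multiplicity pair (C, m) in the clade's census,
#' the quantity 2 * m * s(C, 2m) -- the support the clade would gain if its
#' clusters were duplicated by a polyploidization event -- falling back to
#' m * s(C, m) when no doubled occurrence was observed. Used to pick the
#' representative clade during merging.
#'
#' @param tree a `multree`.
#' @param u node id of the clade root.
#' @param map cluster frequency map from [compute_sorted_clusters()], or
#'   `NULL` (all scores 0; ties then resolve by discovery order).
#' @return Non-negative numeric.
#' @export
compute_clade_score <- function(tree, u, map) {
  if (is.null(map)) return(0)
  total <- 0
  for (rec in clusters_of_tree(subtree(tree, u))) {
    m <- rec$multiplicity
    sc <- 2 * m * cluster_frequency(map, rec$cluster, 2L * m)
    if (sc == 0) sc <- m * cluster_frequency(map, rec$cluster, m)
    total <- total + sc
  }
  total
}

#' Fold a MUL-tree into a phylogenetic network
#'
#' Processes nodes height by height, from the root height down to the
#' leaves. Within each height's FIFO queue, the front node is compared to
#' every remaining same-height node; all near-isomorphic clades (equal
#' cluster multiset, codes equal or edit distance within `delta`) are
#' collected and merged: the clade with the highest support score becomes
#' the representative (ties: the last one found, replicating the >= update
#' rule), a reticulation node is subdivided into its parent edge, every
#' other clade is pruned and its parent re-wired into the reticulation.
#' Representative children are enqueued at their original heights; pruned
#' clades' children never are, and heights, codes and clusters are those of
#' the input tree throughout (static schedule). Merging k > 2 clades
#' yields one reticulation of in-degree k; see
#' [binarize_reticulations()] for a binary rewrite. A uniquely-labeled
#' input passes through unchanged (zero reticulations).
#'
#' @param tree a `multree` (typically the consensus MUL-tree).
#' @param delta near-isomorphism threshold in [0, 1]; 0.3 is a robust
#'   default across ILS levels, 0 reproduces strict folding.
#' @param map cluster frequency map for clade scores, or `NULL`.
#' @param log function called with one character line per merge event, or
#'   `NULL`.
#' @return A `phylonet` whose leaves are the distinct labels of the input.
#' @export
fold <- function(tree, delta = 0.3, map = NULL, log = NULL) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  n0 <- length(tree$parent)
  heights <- node_heights(tree)
  codes <- assign_codes(tree)
  clusters <- node_clusters(tree)
  H <- heights[tree$root]

  # mutable graph state (ids beyond n0 are reticulations added here)
  parents <- lapply(seq_len(n0), function(v)
    if (is.na(tree$parent[v])) integer(0) else tree$parent[v])
  children <- tree$children
  live <- rep(TRUE, n0)
  is_ret <- logical(n0)
  labels <- tree$label

  new_ret <- function() {
    id <- length(parents) + 1L
    parents[[id]] <<- integer(0)
    children[[id]] <<- integer(0)
    live[id] <<- TRUE
    is_ret[id] <<- TRUE
    labels[id] <<- NA_character_
    id
  }
  kill_from <- function(v) {                 # v has just lost a parent edge
    if (length(parents[[v]]) > 0L) return()
    live[v] <<- FALSE
    kids <- children[[v]]                    # parallel edges: one per entry
    children[[v]] <<- integer(0)
    for (c in kids) {
      parents[[c]] <<- parents[[c]][-match(v, parents[[c]])]
      # a shared (reticulation) child survives while other parents remain
      kill_from(c)
    }
  }

  queues <- rep(list(integer(0)), H + 1L)
  queues[[H + 1L]] <- tree$root
  enqueued <- logical(n0)
  enqueued[tree$root] <- TRUE
  score_cache <- rep(NA_real_, n0)
  score_of <- function(u) {
    if (is.na(score_cache[u]))
      score_cache[u] <<- compute_clade_score(tree, u, map)
    score_cache[u]
  }

  for (h in seq(H, 0L)) {
    while (length(queues[[h + 1L]]) > 0L) {
      u <- queues[[h + 1L]][1]
      queues[[h + 1L]] <- queues[[h + 1L]][-1]
      if (!live[u]) next
      # find near-isomorphic clades among the remaining queue members
      rest <- queues[[h + 1L]]
      hits <- integer(0)
      for (v in rest) {
        if (live[v] &&
            are_near_isomorphic(tree, u, v, delta, codes, clusters))
          hits <- c(hits, v)
      }
      if (length(hits) > 0L) {
        queues[[h + 1L]] <- setdiff(queues[[h + 1L]], hits)
        grp <- c(u, hits)
        scores <- vapply(grp, score_of, numeric(1))
        rep_i <- max(which(scores >= cummax(scores)[length(scores)]))
        # literal ">= maxSupport" update: last argmax in discovery order
        rep_node <- grp[rep_i]
        pruned <- setdiff(grp, rep_node)
        if (!is.null(log))
          log(sprintf(
            "merge h=%d cluster={%s} clades=%d rep=%d scores=%s delta=%g",
            h, ms_key(clusters[[u]], ","), length(grp), rep_node,
            paste(format(scores, digits = 4), collapse = "/"), delta))
        r <- new_ret()
        # subdivide the representative's parent edge with r
        p <- parents[[rep_node]][1]
        children[[p]][match(rep_node, children[[p]])] <- r
        parents[[r]] <- p
        parents[[rep_node]] <- r
        children[[r]] <- rep_node
        # prune the others; their parents gain an edge into r
        for (v in pruned) {
          pv <- parents[[v]][1]
          children[[pv]][match(v, children[[pv]])] <- r
          parents[[r]] <- c(parents[[r]], pv)
          parents[[v]] <- parents[[v]][-1]
          kill_from(v)
          # suppress a parent left with a single child (defensive; edge
          # replacement normally preserves out-degree)
          if (live[pv] && !is_ret[pv] && length(children[[pv]]) == 1L &&
              length(parents[[pv]]) > 0L) {
            only <- children[[pv]][1]
            gp <- parents[[pv]][1]
            children[[gp]][match(pv, children[[gp]])] <- only
            parents[[only]][match(pv, parents[[only]])] <- gp
            live[pv] <- FALSE
          }
        }
        next_children <- tree$children[[rep_node]]
      } else {
        next_children <- if (u <= n0) tree$children[[u]] else integer(0)
      }
      for (c in next_children) {
        if (live[c] && !enqueued[c]) {
          enqueued[c] <- TRUE
          queues[[heights[c] + 1L]] <- c(queues[[heights[c] + 1L]], c)
        }
      }
    }
  }

  ids <- which(live)
  remap <- match(seq_along(live), ids)
  edges <- matrix(integer(0), ncol = 2)
  for (p in ids) {
    for (c in children[[p]])
      edges <- rbind(edges, c(remap[p], remap[c]))
  }
  phylonet(edges, labels[ids], root = remap[tree$root])
}

#' Rewrite high in-degree reticulations as binary chains
#'
#' A reticulation with k > 2 incoming edges is replaced by a deterministic
#' left-leaning chain of k - 1 binary reticulations (first two parents at
#' the bottom, later parents stacked above).
#'
#' @param net a `phylonet`.
#' @return A `phylonet` in which every reticulation has in-degree 2.
#' @export
binarize_reticulations <- function(net) {
  repeat {
    indeg <- tabulate(net$edge[, 2], length(net$label))
    v <- which(indeg > 2L)
    if (length(v) == 0L) return(net)
    v <- v[1]
    ek <- which(net$edge[, 2] == v)
    # pull the first two parent edges down onto a fresh binary reticulation
    # feeding v; repeating this yields a left-leaning chain
    newid <- length(net$label) + 1L
    label <- c(net$label, NA_character_)
    edge <- net$edge
    edge[ek[c(1L, 2L)], 2] <- newid
    edge <- rbind(edge, c(newid, v))
    net <- phylonet(edge, label, c(net$edge_length, NA_real_))
  }
}
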