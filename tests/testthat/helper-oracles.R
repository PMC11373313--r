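# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they validate one.

# brute-force count of directed root-to-leaf-label paths in a network
oracle_path_counts <- function(net) {
  kids <- mulfold:::net_children(net)
  leaves <- mulfold:::net_leaves(net)
  counts <- integer(0)
  walk <- function(v) {
    if (length(kids[[v]]) == 0L) return(net$label[v])
    unlist(lapply(kids[[v]], walk))
  }
  labs <- walk(net$root)
  table(labs)
}

# cluster multiset census (keys, counted with node multiplicity) computed
# directly from an ape "phylo" object, independent of mulfold's parser
ape_cluster_census <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nodes <- sort(unique(phy$edge[, 1]))
  vapply(nodes, function(v) {
    tips <- integer(0)
    frontier <- v
    while (length(frontier) > 0L) {
      u <- frontier[1]; frontier <- frontier[-1]
      if (u <= ntip) tips <- c(tips, u)
      else frontier <- c(frontier, phy$edge[phy$edge[, 1] == u, 2])
    }
    paste(sort(phy$tip.label[tips]), collapse = "\x1f")
  }, character(1))
}

# exhaustive enumeration of all rooted binary resolutions of d child
# groups; returns the maximum achievable total weight (oracle for the
# refine DP)
oracle_best_resolution <- function(group_clusters, wfun) {
  enumerate <- function(items) {
    # items: list of list(cl = multiset, w = accumulated weight)
    if (length(items) == 1L) return(items[[1]]$w)
    best <- -Inf
    for (i in seq_len(length(items) - 1L)) {
      for (j in seq(i + 1L, length(items))) {
        un <- mulfold:::ms_sum(items[[i]]$cl, items[[j]]$cl)
        merged <- list(cl = un,
                       w = items[[i]]$w + items[[j]]$w +
                         if (length(items) > 2L) wfun(un) else 0)
        rest <- items[-c(i, j)]
        best <- max(best, enumerate(c(rest, list(merged))))
      }
    }
    best
  }
  items <- lapply(group_clusters, function(cl) list(cl = cl, w = 0))
  enumerate(items)
}

# random gene-tree batch over a small label pool (multilabeled)
random_trees <- function(n, labels) {
  lapply(seq_len(n), function(i)
    rmultree(sample(labels, sample(seq(3, length(labels)), 1))))
}

random_cluster_graph <- function(labels = c("a", "a", "b", "b", "c", "d"),
                                 n_trees = 4, max_vertices = 14) {
  trees <- random_trees(n_trees, labels)
  sc <- compute_sorted_clusters(trees)
  L <- mulfold:::infer_target_multiset(trees)
  recs <- sc$records[seq_len(min(max_vertices, length(sc$records)))]
  suppressWarnings(build_graph(recs, L))
}
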