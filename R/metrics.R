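#' Normalized edit distance between whole MUL-trees
#'
#' [normalized_ged()] applied to complete trees: 0 iff the trees are
#' isomorphic, 1 is the cost of replacing one tree by the other outright.
#'
#' @param t1,t2 `multree` objects.
#' @return Numeric in [0, 1].
#' @export
multree_distance <- function(t1, t2) {
  normalized_ged(t1, t2)
}

# path-multiplicity label of every node: counts of directed paths from the
# node to each taxon, in the order of `taxa`
path_multiplicity_labels <- function(net, taxa) {
  kids <- net_children(net)
  n <- length(net$label)
  counts <- matrix(0, n, length(taxa))
  ord <- topo_order(net)
  for (v in rev(ord)) {
    if (length(kids[[v]]) == 0L) {
      counts[v, match(net$label[v], taxa)] <- 1
    } else {
      for (c in kids[[v]]) counts[v, ] <- counts[v, ] + counts[c, ]
    }
  }
  apply(counts, 1, paste, collapse = ",")
}

#' Path-multiplicity distance between networks
#'
#' Labels every node of each network with its vector of root-to-taxon path
#' counts (for a tree node this reduces to its cluster; the root's vector
#' is the leaf multiset of the unfolded MUL-tree), then compares the two
#' multisets of node labels: distance = |multiset symmetric difference| /
#' (|V1| + |V2|). Zero for isomorphic networks. Accepts `multree` inputs
#' (converted to tree-shaped networks).
#'
#' @param n1,n2 `phylonet` (or tree-shaped `multree`) objects on the same
#'   taxon set.
#' @return Numeric in [0, 1].
#' @export
network_distance <- function(n1, n2) {
  if (inherits(n1, "multree")) n1 <- as_phylonet(n1)
  if (inherits(n2, "multree")) n2 <- as_phylonet(n2)
  tax1 <- sort(n1$label[net_leaves(n1)], method = "radix")
  tax2 <- sort(n2$label[net_leaves(n2)], method = "radix")
  if (!identical(tax1, tax2))
    stop("networks are not on the same taxon set")
  l1 <- path_multiplicity_labels(n1, tax1)
  l2 <- path_multiplicity_labels(n2, tax1)
  keys <- unique(c(l1, l2))
  c1 <- vapply(keys, function(k) sum(l1 == k), numeric(1))
  c2 <- vapply(keys, function(k) sum(l2 == k), numeric(1))
  sum(abs(c1 - c2)) / (length(l1) + length(l2))
}

#' Normalized rooted Robinson-Foulds distance for MUL-trees
#'
#' The clade-cluster census of each tree (internal non-root nodes, clusters
#' as label multisets, counted with multiplicity) is compared by multiset
#' symmetric difference, normalized by the total census size of both trees.
#' The natural lift of the rooted RF distance to multilabeled trees; used
#' to quantify gene-tree discordance.
#'
#' @param t1,t2 `multree` objects with equal leaf multisets.
#' @return Numeric in [0, 1]; 0 when both censuses are empty.
#' @export
rooted_rf <- function(t1, t2) {
  if (!ms_equal(leaf_multiset(t1), leaf_multiset(t2)))
    stop("trees are not on the same leaf multiset")
  census <- function(tr) {
    cl <- node_clusters(tr)
    internal <- setdiff(which(lengths(tr$children) > 0L), tr$root)
    vapply(cl[internal], ms_key, character(1))
  }
  a <- census(t1); b <- census(t2)
  if (length(a) + length(b) == 0L) return(0)
  keys <- unique(c(a, b))
  ca <- vapply(keys, function(k) sum(a == k), numeric(1))
  cb <- vapply(keys, function(k) sum(b == k), numeric(1))
  sum(abs(ca - cb)) / (length(a) + length(b))
}
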