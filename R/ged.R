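#' Canonical isomorphism codes
#'
#' Bottom-up canonical form per node: a leaf's code is its label; an
#' internal node's code is `(` + the sorted codes of its children joined by
#' `,` + `)`. Two clades are isomorphic as leaf-labeled rooted trees iff
#' their codes are equal, so code comparison replaces explicit isomorphism
#' tests throughout the folding phase.
#'
#' @param tree a `multree`.
#' @return Character vector of codes, one per node id.
#' @export
assign_codes <- function(tree) {
  code <- character(length(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    code[v] <- if (length(ch) == 0L) tree$label[v]
               else paste0("(",
                           paste(sort(code[ch], method = "radix"),
                                 collapse = ","),
                           ")")
  }
  code
}

# graph weight of the subtree below each node: structural nodes plus one
# label vertex per leaf (labels are modeled as attached label vertices, so
# a cherry counts |V| = 5, |E| = 4)
subtree_graph_sizes <- function(tree) {
  sz <- integer(length(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    sz[v] <- if (length(ch) == 0L) 2L else 1L + sum(sz[ch])
  }
  sz
}

# exact minimum-cost assignment of children (square padded LSAP):
# rows = children of u plus "delete" slots, cols = children of v plus
# "insert" slots; deletion/insertion of an unmatched child removes/adds its
# whole subtree (nodes + internal edges + parent edge = 2 * size).
match_children <- function(D, del1, del2) {
  n1 <- length(del1); n2 <- length(del2)
  if (n1 == 0L) return(sum(del2))
  if (n2 == 0L) return(sum(del1))
  big <- sum(del1) + sum(del2) + 1
  M <- matrix(big, n1 + n2, n1 + n2)
  M[seq_len(n1), seq_len(n2)] <- D
  for (i in seq_len(n1)) M[i, n2 + i] <- del1[i]
  for (j in seq_len(n2)) M[n1 + j, j] <- del2[j]
  M[seq(n1 + 1L, n1 + n2), seq(n2 + 1L, n2 + n1)] <- 0
  sol <- clue::solve_LSAP(M)
  sum(M[cbind(seq_len(n1 + n2), as.integer(sol))])
}

#' Normalized tree edit distance between rooted clades
#'
#' A fixed, documented edit model on rooted leaf-labeled trees. Each leaf
#' label is modeled as a label vertex hanging off its leaf (a cherry thus
#' counts |V| = 5, |E| = 4). Matched nodes cost 0 when both are internal
#' or both are leaves with equal labels; a leaf-label mismatch substitutes
#' the label vertex (cost 1); matching a leaf against an internal node
#' deletes the label vertex and its edge (cost 2). An unmatched subtree is
#' deleted/inserted wholesale at unit cost per node and per edge (parent
#' edge included). Children of matched nodes are matched optimally by
#' Hungarian assignment, so the distance is exact at every input size (the
#' model is polynomial). The raw distance is normalized by
#' (|V1| + |E1| + |V2| + |E2|), the cost of deleting one tree entirely and
#' inserting the other, giving a value in [0, 1] that is 0 iff the clades
#' are isomorphic.
#'
#' @param t1,t2 `multree` objects (clades).
#' @return Numeric in [0, 1].
#' @examples
#' normalized_ged(parse_newick("(a,b);"), parse_newick("(a,c);"))  # 1/18
#' @export
normalized_ged <- function(t1, t2) {
  sz1 <- subtree_graph_sizes(t1); sz2 <- subtree_graph_sizes(t2)
  rec <- function(u, v) {
    l1 <- is_leaf(t1, u); l2 <- is_leaf(t2, v)
    sub <- if (l1 && l2) {
      if (identical(t1$label[u], t2$label[v])) 0 else 1
    } else if (l1 != l2) 2 else 0
    c1 <- t1$children[[u]]; c2 <- t2$children[[v]]
    if (length(c1) == 0L && length(c2) == 0L) return(sub)
    D <- matrix(0, length(c1), length(c2))
    for (i in seq_along(c1))
      for (j in seq_along(c2))
        D[i, j] <- rec(c1[i], c2[j])
    sub + match_children(D, 2 * sz1[c1], 2 * sz2[c2])
  }
  # |V| + |E| of a rooted tree with label vertices = 2 * weight - 1
  denom <- (2 * sz1[t1$root] - 1) + (2 * sz2[t2$root] - 1)
  rec(t1$root, t2$root) / denom
}
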