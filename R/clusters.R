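#' Cluster census of a single MUL-tree
#'
#' The cluster of a node is the multiset of leaf labels below it. The census
#' enumerates the distinct cluster multisets induced by the internal nodes
#' (root included, leaves excluded) of one tree, together with their
#' multiplicity: the number of internal nodes inducing exactly that multiset.
#'
#' @param tree a `multree`.
#' @return List of records, each `list(cluster = <label_multiset>,
#'   multiplicity = <int>)`.
#' @examples
#' clusters_of_tree(parse_newick("((x,z)u,(x,y,z)v)w;"))
#' @export
clusters_of_tree <- function(tree) {
  cl <- node_clusters(tree)
  internal <- which(lengths(tree$children) > 0L)
  keys <- vapply(cl[internal], ms_key, character(1))
  uk <- unique(keys)
  lapply(uk, function(k) {
    list(cluster = cl[[internal[match(k, keys)]]],
         multiplicity = sum(keys == k))
  })
}

rec_key <- function(cluster, multiplicity) {
  paste0(ms_key(cluster), "|", multiplicity)
}

#' Cross-tree cluster frequencies
#'
#' For a gene-tree collection, counts for every cluster-multiplicity pair
#' (C, m) the number of trees whose census contains C at exactly
#' multiplicity m (exact-multiplicity semantics: a tree where C appears
#' twice contributes to (C, 2) but not to (C, 1)). Records are sorted in
#' descending frequency; ties break by larger multiplicity, then larger
#' cluster size, then lexicographic label order, so the output is a total
#' order reproducible across platforms.
#'
#' @param gene_trees non-empty list of `multree` objects.
#' @return List with `records` (each `list(cluster, multiplicity,
#'   frequency)`, sorted) and `map`, a cluster frequency map usable with
#'   [cluster_frequency()].
#' @export
compute_sorted_clusters <- function(gene_trees) {
  if (length(gene_trees) == 0L) stop("need at least one gene tree")
  tally <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (tr in gene_trees) {
    for (rec in clusters_of_tree(tr)) {
      k <- rec_key(rec$cluster, rec$multiplicity)
      cnt <- if (is.null(tally[[k]])) 0L else tally[[k]]
      tally[[k]] <- cnt + 1L
      if (cnt == 0L) store[[k]] <- rec
    }
  }
  keys <- ls(tally, sorted = TRUE)
  records <- lapply(keys, function(k) {
    rec <- store[[k]]
    list(cluster = rec$cluster, multiplicity = rec$multiplicity,
         frequency = tally[[k]])
  })
  freq <- vapply(records, `[[`, integer(1), "frequency")
  mult <- vapply(records, `[[`, integer(1), "multiplicity")
  size <- vapply(records, function(r) ms_size(r$cluster), integer(1))
  lex <- vapply(records, function(r) ms_key(r$cluster), character(1))
  ord <- order(-freq, -mult, -size, lex, method = "radix")
  records <- records[ord]
  map <- stats::setNames(vapply(records, `[[`, integer(1), "frequency"),
                         vapply(records, function(r)
                           rec_key(r$cluster, r$multiplicity), character(1)))
  list(records = records, map = map)
}

#' Look up the frequency of a cluster-multiplicity pair
#'
#' @param map the `map` component of [compute_sorted_clusters()].
#' @param cluster a `label_multiset`.
#' @param multiplicity positive integer.
#' @return Integer frequency; 0 for absent pairs.
#' @export
cluster_frequency <- function(map, cluster, multiplicity) {
  v <- map[rec_key(cluster, multiplicity)]
  if (is.na(v)) 0L else as.integer(v)
}

#' Filter cluster records by minimum frequency
#'
#' Retains records whose frequency is at least `tau`, preserving order.
#' `tau = 1` is the identity; a threshold above the maximum frequency
#' yields an empty list (the caller must handle it).
#'
#' @param records sorted record list from [compute_sorted_clusters()].
#' @param tau minimum frequency (>= 1).
#' @return Filtered record list.
#' @export
filter_by_frequency <- function(records, tau) {
  stopifnot(tau >= 1)
  Filter(function(r) r$frequency >= tau, records)
}

#' Export a cluster table as a data frame
#'
#' @param records record list.
#' @param alpha cluster-size exponent used for the weight column.
#' @return data.frame with columns cluster, multiplicity, frequency, weight.
#' @export
cluster_table <- function(records, alpha = 0.65) {
  data.frame(
    cluster = vapply(records, function(r) ms_key(r$cluster, sep = ","),
                     character(1)),
    multiplicity = vapply(records, `[[`, integer(1), "multiplicity"),
    frequency = vapply(records, `[[`, integer(1), "frequency"),
    weight = vapply(records, function(r) node_weight(r, alpha), numeric(1)),
    stringsAsFactors = FALSE)
}
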