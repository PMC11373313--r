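#' Rooted phylogenetic networks
#'
#' A `phylonet` is a rooted directed acyclic graph with uniquely labeled
#' leaves. Tree nodes have in-degree at most 1; reticulation nodes
#' (in-degree >= 2) model hybridization/polyploidization events and have
#' out-degree exactly 1. Parallel edges are allowed (a reticulation may
#' receive two edges from the same parent, encoding two subgenome
#' contributions from one lineage). In-degree above 2 is permitted
#' internally; see [binarize_reticulations()].
#'
#' @param edge two-column integer matrix of directed edges (parent, child).
#' @param label character vector of node labels (`NA` for unnamed internal
#'   nodes; leaves must be labeled and pairwise distinct).
#' @param edge_length optional numeric vector of edge lengths.
#' @param root integer id of the root node.
#' @return An object of class `phylonet`.
#' @export
phylonet <- function(edge, label, edge_length = rep(NA_real_, nrow(edge)),
                     root = NULL) {
  edge <- matrix(as.integer(edge), ncol = 2)
  n <- length(label)
  indeg <- tabulate(edge[, 2], n)
  if (is.null(root)) {
    r <- setdiff(seq_len(n), edge[, 2])
    if (length(r) != 1L) stop("network must have exactly one root")
    root <- r
  }
  obj <- structure(list(edge = edge, label = as.character(label),
                        edge_length = as.numeric(edge_length),
                        root = as.integer(root)),
                   class = "phylonet")
  validate_phylonet(obj)
  obj
}

net_children <- function(net) {
  n <- length(net$label)
  out <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(net$edge)))
    out[[net$edge[k, 1]]] <- c(out[[net$edge[k, 1]]], net$edge[k, 2])
  out
}

net_parents <- function(net) {
  n <- length(net$label)
  out <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(net$edge)))
    out[[net$edge[k, 2]]] <- c(out[[net$edge[k, 2]]], net$edge[k, 1])
  out
}

net_leaves <- function(net) {
  setdiff(seq_along(net$label), unique(net$edge[, 1]))
}

#' @rdname phylonet
#' @param net a `phylonet`.
#' @export
n_reticulations <- function(net) {
  indeg <- tabulate(net$edge[, 2], length(net$label))
  sum(indeg >= 2L)
}

validate_phylonet <- function(net) {
  n <- length(net$label)
  indeg <- tabulate(net$edge[, 2], n)
  outdeg <- tabulate(net$edge[, 1], n)
  if (indeg[net$root] != 0L) stop("root has incoming edges")
  # acyclicity + reachability via Kahn's algorithm from the root
  order <- topo_order(net)
  if (length(order) != n) stop("network is cyclic or not fully reachable")
  leaves <- which(outdeg == 0L)
  labs <- net$label[leaves]
  if (anyNA(labs) || anyDuplicated(labs))
    stop("leaves must carry pairwise distinct labels")
  ret <- which(indeg >= 2L)
  if (any(outdeg[ret] != 1L))
    stop("reticulation nodes must have out-degree 1")
  invisible(net)
}

# topological order (parents before children); errors never raised here
topo_order <- function(net) {
  n <- length(net$label)
  indeg <- tabulate(net$edge[, 2], n)
  kids <- net_children(net)
  queue <- net$root
  out <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in kids[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  # nodes never reached (isolated) are dropped; caller compares lengths
  out
}

#' @export
print.phylonet <- function(x, ...) {
  cat("<phylonet> ", length(net_leaves(x)), " leaves, ",
      n_reticulations(x), " reticulation(s): ", write_enewick(x), "\n",
      sep = "")
  invisible(x)
}

## ------------------------------------------------------- extended Newick --

#' Parse and write extended Newick networks
#'
#' The `#H<k>` dialect: each reticulation node is written once in full (its
#' subtree at the first occurrence, e.g. `(b)#H1`) and referenced elsewhere
#' by its bare tag `#H1`. A tree-shaped input (no tags) yields a network
#' with zero reticulations.
#'
#' @param text a single extended Newick expression terminated by `;`.
#' @return `parse_enewick()` returns a `phylonet`; `write_enewick()` a
#'   string.
#' @examples
#' net <- parse_enewick("((a,(b)#H1),(#H1,c));")
#' n_reticulations(net)
#' write_newick(unfold(net))
#' @export
parse_enewick <- function(text) {
  raw <- nwk_parse_raw(text)
  n <- length(raw$parent)
  tag <- rep(NA_character_, n)
  m <- regmatches(raw$label, regexec("^(.*)#H?([0-9]+)$", raw$label))
  for (v in seq_len(n)) {
    if (!is.na(raw$label[v]) && length(m[[v]]) == 3L) {
      tag[v] <- m[[v]][3]
      raw$label[v] <- if (nzchar(m[[v]][2])) m[[v]][2] else NA_character_
    }
  }
  # for each tag: exactly one defining occurrence (with children)
  keep <- rep(TRUE, n)
  redirect <- seq_len(n)
  for (tg in unique(stats::na.omit(tag))) {
    occ <- which(tag == tg)
    def <- occ[lengths(raw$children[occ]) > 0L]
    if (length(def) == 0L)
      stop("hybrid tag #H", tg, " referenced but never defined")
    if (length(def) > 1L)
      stop("hybrid tag #H", tg, " defined more than once")
    refs <- setdiff(occ, def)
    keep[refs] <- FALSE
    redirect[refs] <- def
  }
  # build edges, redirecting reference leaves to the defining node
  edges <- matrix(integer(0), ncol = 2)
  elen <- numeric(0)
  for (v in seq_len(n)) {
    for (c in raw$children[[v]]) {
      edges <- rbind(edges, c(v, redirect[c]))
      elen <- c(elen, raw$length[c])
    }
  }
  ids <- which(keep)
  remap <- match(seq_len(n), ids)
  edges <- matrix(remap[edges], ncol = 2)
  net <- phylonet(edges, raw$label[ids], elen, root = remap[raw$root])
  net
}

#' @rdname parse_enewick
#' @param net a `phylonet`.
#' @param digits significant digits for edge lengths.
#' @export
write_enewick <- function(net, digits = 10) {
  kids <- net_children(net)
  indeg <- tabulate(net$edge[, 2], length(net$label))
  ret <- which(indeg >= 2L)
  tagno <- integer(length(net$label))
  next_tag <- 0L
  written <- logical(length(net$label))
  edge_len <- function(p, c) {
    k <- which(net$edge[, 1] == p & net$edge[, 2] == c)
    if (length(k) == 0L) NA_real_ else net$edge_length[k[1]]
  }
  emit <- function(v, len) {
    suffix <- if (!is.na(len))
      paste0(":", format(len, digits = digits, scientific = FALSE)) else ""
    if (v %in% ret) {
      if (!written[v]) {
        written[v] <<- TRUE
        next_tag <<- next_tag + 1L
        tagno[v] <<- next_tag
        inner <- paste(vapply(kids[[v]],
                              function(c) emit(c, edge_len(v, c)),
                              character(1)), collapse = ",")
        lab <- if (!is.na(net$label[v])) net$label[v] else ""
        return(paste0("(", inner, ")", lab, "#H", tagno[v], suffix))
      }
      return(paste0("#H", tagno[v], suffix))
    }
    ch <- kids[[v]]
    if (length(ch) == 0L) return(paste0(net$label[v], suffix))
    inner <- paste(vapply(ch, function(c) emit(c, edge_len(v, c)),
                          character(1)), collapse = ",")
    lab <- if (!is.na(net$label[v])) net$label[v] else ""
    paste0("(", inner, ")", lab, suffix)
  }
  paste0(emit(net$root, NA_real_), ";")
}

## ---------------------------------------------------------------- unfold --

#' Unfold a network into its multilabeled tree
#'
#' Every reticulation node of in-degree k is expanded into k independent
#' copies of the sub-DAG below it, one per incoming edge. Chain nodes of
#' out-degree 1 (the reticulations themselves, once duplicated) are
#' suppressed, summing branch lengths, so the result is a proper MUL-tree.
#' The copy number of label x in the result equals the number of directed
#' root-to-x paths in the network.
#'
#' @param network a `phylonet`.
#' @return A `multree`.
#' @export
unfold <- function(network) {
  kids <- net_children(network)
  elen_map <- new.env(parent = emptyenv())
  get_len <- function(p, c, occurrence) {
    k <- which(network$edge[, 1] == p & network$edge[, 2] == c)
    network$edge_length[k[min(occurrence, length(k))]]
  }
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0); acc$children <- list()
  acc$label <- character(0); acc$length <- numeric(0)
  add_node <- function(lab, len) {
    id <- length(acc$parent) + 1L
    acc$parent[id] <- NA_integer_
    acc$children[[id]] <- integer(0)
    acc$label[id] <- lab
    acc$length[id] <- len
    id
  }
  # copy node v arriving with accumulated branch length `len`
  rec <- function(v, len) {
    ch <- kids[[v]]
    while (length(ch) == 1L) {      # suppress out-degree-1 chain nodes
      c1 <- ch[1]
      l1 <- get_len(v, c1, 1L)
      len <- if (is.na(len)) l1 else if (is.na(l1)) len else len + l1
      v <- c1
      ch <- kids[[v]]
    }
    if (length(ch) == 0L) return(add_node(network$label[v], len))
    id <- add_node(network$label[v], len)
    seen <- integer(0)
    kid_ids <- integer(0)
    for (c in ch) {
      seen <- c(seen, c)
      occ <- sum(seen == c)        # parallel edges: occurrence index
      kid_ids <- c(kid_ids, rec(c, get_len(v, c, occ)))
    }
    for (k in kid_ids) acc$parent[k] <- id
    acc$children[[id]] <- kid_ids
    id
  }
  root <- rec(network$root, NA_real_)
  multree(acc$parent, acc$children, acc$label, acc$length, root)
}

# convert a tree-shaped multree to a phylonet (used by metrics)
as_phylonet <- function(tree) {
  n <- length(tree$parent)
  edges <- cbind(tree$parent, seq_len(n))
  edges <- edges[!is.na(tree$parent), , drop = FALSE]
  phylonet(edges, tree$label, tree$length[edges[, 2]], root = tree$root)
}
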