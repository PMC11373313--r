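#' Rooted multilabeled trees
#'
#' A `multree` is a rooted tree whose leaves carry taxon labels that need not
#' be unique: each repeated label represents one subgenome copy of a polyploid
#' taxon. A uniquely-labeled phylogenetic tree is the special case in which
#' every label occurs once. Internal structure is stored flat: integer node
#' ids with a parent pointer, ordered child lists, optional node labels and
#' optional branch lengths (coalescent units when produced by the simulator;
#' ignored by all inference operations, which are topology-only).
#'
#' @param parent integer vector, `NA` for the root.
#' @param children list of integer vectors (ordered as parsed).
#' @param label character vector; leaves must be labeled, internal labels
#'   optional (`NA`).
#' @param length numeric vector of branch lengths above each node (`NA` when
#'   absent).
#' @param root integer id of the root.
#' @return An object of class `multree`.
#' @export
multree <- function(parent, children, label,
                    length = rep(NA_real_, base::length(parent)),
                    root = which(is.na(parent))) {
  obj <- structure(list(parent = as.integer(parent), children = children,
                        label = as.character(label),
                        length = as.numeric(length),
                        root = as.integer(root)),
                   class = "multree")
  validate_multree(obj)
  obj
}

validate_multree <- function(tree) {
  n <- length(tree$parent)
  if (length(tree$root) != 1L || sum(is.na(tree$parent)) != 1L)
    stop("multree must have exactly one root")
  if (!is.na(tree$parent[tree$root]))
    stop("root must have no parent")
  for (v in seq_len(n)) {
    for (c in tree$children[[v]]) {
      if (is.na(tree$parent[c]) || tree$parent[c] != v)
        stop("parent/children mismatch at node ", c)
    }
  }
  po <- postorder(tree)
  if (length(po) != n) stop("not all nodes reachable from root")
  leaves <- which(lengths(tree$children) == 0L)
  if (any(is.na(tree$label[leaves])) || any(!nzchar(tree$label[leaves])))
    stop("all leaves must carry labels")
  invisible(tree)
}

#' @export
print.multree <- function(x, ...) {
  cat("<multree> ", n_leaves(x), " leaves, ", length(x$parent), " nodes: ",
      write_newick(x), "\n", sep = "")
  invisible(x)
}

is_leaf <- function(tree, v) length(tree$children[[v]]) == 0L

leaves_of <- function(tree) which(lengths(tree$children) == 0L)

n_leaves <- function(tree) sum(lengths(tree$children) == 0L)

# depth-first postorder (children before parents), children in stored order
postorder <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n); k <- 0L
  stack <- tree$root; state <- integer(0)
  # iterative: push node twice
  todo <- list(c(tree$root, 0L))
  while (length(todo) > 0L) {
    top <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    v <- top[1]; seen <- top[2]
    if (seen == 1L) {
      k <- k + 1L; out[k] <- v
    } else {
      todo[[length(todo) + 1L]] <- c(v, 1L)
      ch <- tree$children[[v]]
      for (i in rev(seq_along(ch)))
        todo[[length(todo) + 1L]] <- c(ch[i], 0L)
    }
  }
  out[seq_len(k)]
}

preorder <- function(tree) rev(postorder(tree))

#' Leaf label multiset of a tree
#'
#' @param tree a `multree`.
#' @return A [label_multiset()] counting each taxon label with multiplicity.
#' @export
leaf_multiset <- function(tree) {
  label_multiset(tree$label[leaves_of(tree)])
}

#' Topological node heights
#'
#' Height of a leaf is 0; height of an internal node is one more than the
#' maximum height among its children (edge count on the longest node-to-leaf
#' path). Branch lengths play no role: the folding algorithm schedules its
#' merge queues by discrete levels.
#'
#' @param tree a `multree`.
#' @return Integer vector of heights, one per node id.
#' @export
node_heights <- function(tree) {
  h <- integer(length(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    h[v] <- if (length(ch) == 0L) 0L else 1L + max(h[ch])
  }
  h
}

# node depths (root = 0)
node_depths <- function(tree) {
  d <- integer(length(tree$parent))
  for (v in preorder(tree)) {
    p <- tree$parent[v]
    d[v] <- if (is.na(p)) 0L else d[p] + 1L
  }
  d
}

# label multiset (as plain named int) below every node
node_clusters <- function(tree) {
  n <- length(tree$parent)
  labs <- vector("list", n)
  for (v in postorder(tree)) {
    ch <- tree$children[[v]]
    labs[[v]] <- if (length(ch) == 0L) tree$label[v]
                 else unlist(labs[ch], use.names = FALSE)
  }
  lapply(labs, label_multiset)
}

#' Extract the clade below a node as a standalone tree
#'
#' @param tree a `multree`.
#' @param v node id.
#' @return A `multree` rooted at `v` (node ids renumbered).
#' @export
subtree <- function(tree, v) {
  keep <- integer(0)
  stack <- v
  while (length(stack) > 0L) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    keep <- c(keep, u)
    stack <- c(stack, tree$children[[u]])
  }
  keep <- sort(keep)
  idx <- match(seq_along(tree$parent), keep)   # old id -> new id
  parent <- tree$parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, idx[parent])
  parent[match(v, keep)] <- NA_integer_
  children <- lapply(tree$children[keep], function(ch) idx[ch])
  multree(parent, children, tree$label[keep], tree$length[keep],
          root = match(v, keep))
}

## ---------------------------------------------------------------- Newick --

# cursor-based recursive-descent parser shared by newick and extended newick
nwk_cursor <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$i <- 1L
  env
}

nwk_peek <- function(cur) {
  if (cur$i > length(cur$chars)) "" else cur$chars[cur$i]
}

nwk_skip <- function(cur) {
  repeat {
    ch <- nwk_peek(cur)
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      cur$i <- cur$i + 1L
    } else if (ch == "[") {               # bracketed comment: ignore
      while (nwk_peek(cur) != "]") {
        if (nwk_peek(cur) == "")
          stop("unterminated comment at offset ", cur$i)
        cur$i <- cur$i + 1L
      }
      cur$i <- cur$i + 1L
    } else break
  }
}

nwk_label <- function(cur) {
  nwk_skip(cur)
  stops <- c("(", ")", ",", ":", ";", "[", " ", "\t", "\n", "\r", "")
  out <- character(0)
  while (!(nwk_peek(cur) %in% stops)) {
    out <- c(out, cur$chars[cur$i])
    cur$i <- cur$i + 1L
  }
  paste(out, collapse = "")
}

nwk_number <- function(cur) {
  nwk_skip(cur)
  out <- character(0)
  while (grepl("[-+0-9.eE]", nwk_peek(cur))) {
    out <- c(out, cur$chars[cur$i])
    cur$i <- cur$i + 1L
  }
  if (length(out) == 0L)
    stop("expected branch length at offset ", cur$i)
  as.numeric(paste(out, collapse = ""))
}

# raw parse: returns flat vectors; hybrid tags (if any) left inside labels
nwk_parse_raw <- function(text) {
  cur <- nwk_cursor(text)
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0); acc$children <- list()
  acc$label <- character(0); acc$length <- numeric(0)
  new_node <- function() {
    id <- length(acc$parent) + 1L
    acc$parent[id] <- NA_integer_
    acc$children[[id]] <- integer(0)
    acc$label[id] <- NA_character_
    acc$length[id] <- NA_real_
    id
  }
  read_clade <- function() {
    nwk_skip(cur)
    if (nwk_peek(cur) == "(") {
      cur$i <- cur$i + 1L
      kids <- integer(0)
      repeat {
        kids <- c(kids, read_clade())
        nwk_skip(cur)
        ch <- nwk_peek(cur)
        if (ch == ",") { cur$i <- cur$i + 1L; next }
        if (ch == ")") { cur$i <- cur$i + 1L; break }
        if (ch == "")
          stop("unbalanced parentheses: input ended at offset ", cur$i)
        stop("unexpected character '", ch, "' at offset ", cur$i)
      }
      v <- new_node()
      lab <- nwk_label(cur)
      if (nzchar(lab)) acc$label[v] <- lab
      for (k in kids) acc$parent[k] <- v
      acc$children[[v]] <- kids
    } else {
      lab <- nwk_label(cur)
      if (!nzchar(lab))
        stop("empty leaf label at offset ", cur$i)
      v <- new_node()
      acc$label[v] <- lab
    }
    nwk_skip(cur)
    if (nwk_peek(cur) == ":") {
      cur$i <- cur$i + 1L
      acc$length[v] <- nwk_number(cur)
    }
    v
  }
  root <- read_clade()
  nwk_skip(cur)
  if (nwk_peek(cur) != ";")
    stop("expected ';' at offset ", cur$i)
  cur$i <- cur$i + 1L
  nwk_skip(cur)
  if (nwk_peek(cur) != "")
    stop("trailing characters at offset ", cur$i)
  list(parent = acc$parent, children = acc$children, label = acc$label,
       length = acc$length, root = root)
}

#' Parse and write Newick trees
#'
#' Repeated leaf labels are permitted (multilabeled trees). Bracketed
#' comments are ignored; internal node names and branch lengths are optional
#' and round-tripped when present. Parse errors report the character offset.
#'
#' @param text a single Newick expression terminated by `;`.
#' @return `parse_newick()` returns a `multree`; `write_newick()` a string.
#' @examples
#' t <- parse_newick("((x,z)u,(x,y,z)v)w;")
#' leaf_multiset(t)
#' write_newick(t)
#' @export
parse_newick <- function(text) {
  raw <- nwk_parse_raw(text)
  multree(raw$parent, raw$children, raw$label, raw$length, raw$root)
}

#' @rdname parse_newick
#' @param tree a `multree`.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, digits = 10) {
  emit <- function(v) {
    ch <- tree$children[[v]]
    s <- if (length(ch) == 0L) tree$label[v]
         else paste0("(", paste(vapply(ch, emit, character(1)),
                                collapse = ","),
                     ")", if (!is.na(tree$label[v])) tree$label[v] else "")
    if (!is.na(tree$length[v]))
      s <- paste0(s, ":", format(tree$length[v], digits = digits,
                                 scientific = FALSE))
    s
  }
  paste0(emit(tree$root), ";")
}

#' Read gene trees from a file, one Newick per line
#'
#' @param path file path; blank lines are skipped.
#' @return List of `multree` objects.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trees in ", path)
  lapply(lines, parse_newick)
}

#' @rdname read_gene_trees
#' @param trees list of `multree` objects.
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}
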