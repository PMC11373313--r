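#' Multispecies coalescent model on a species MUL-tree
#'
#' The stated world of the simulator: allopolyploid gene flow enters only
#' through the MUL-tree (each subgenome is an independent lineage source;
#' the species MUL-tree is the unfolded network), and gene trees arise from
#' the standard multispecies coalescent on it. Branch lengths are in
#' coalescent units; ILS level is set entirely by branch lengths. Leaves
#' without a branch length are given length 0 (pendant lengths are
#' irrelevant with one sample per leaf). Node ages are computed as maximum
#' root-to-leaf depths, so the species tree should be ultrametric: on a
#' non-ultrametric tree the shorter path is implicitly stretched.
#'
#' @param species_multree a `multree` with branch lengths.
#' @param samples_per_leaf number of sampled individuals per leaf (default
#'   1, matching typical usage).
#' @return An object of class `msc_model`.
#' @export
msc_model <- function(species_multree, samples_per_leaf = 1L) {
  stopifnot(samples_per_leaf >= 1L)
  len <- species_multree$length
  internal_missing <- which(is.na(len) &
                            seq_along(len) != species_multree$root &
                            lengths(species_multree$children) > 0L)
  if (length(internal_missing) > 0L)
    stop("species tree internal branches must have lengths")
  structure(list(species_multree = species_multree,
                 samples_per_leaf = as.integer(samples_per_leaf)),
            class = "msc_model")
}

#' @export
print.msc_model <- function(x, ...) {
  cat("<msc_model> on ", write_newick(x$species_multree), " (",
      x$samples_per_leaf, " sample(s)/leaf)\n", sep = "")
  invisible(x)
}

# independent per-gene substream: reproducible per (seed, i) regardless of
# simulation order; kept below 2^31
gene_seed <- function(seed, i) {
  ((as.double(seed) %% 1000003) * 2027 + i * 7919) %% 2147483647
}

#' Simulate multilabeled gene trees under the coalescent
#'
#' For each gene, one lineage starts at every leaf instance (times
#' samples_per_leaf); within each species branch, lineages coalesce at rate
#' 1 per pair in coalescent time, truncated at the branch length; surviving
#' lineages coalesce without bound in the root branch. Gene-tree leaves
#' carry the species labels, so duplicated species leaves yield
#' multilabeled gene trees. Deterministic given `seed`; gene i draws from
#' an independent substream of (seed, i).
#'
#' @param model an `msc_model`.
#' @param n number of gene trees.
#' @param seed integer seed.
#' @return List of `multree` gene trees with coalescent-time branch
#'   lengths.
#' @export
simulate_gene_trees <- function(model, n, seed) {
  sp <- model$species_multree
  k <- model$samples_per_leaf
  ages <- numeric(length(sp$parent))
  for (v in postorder(sp)) {
    ch <- sp$children[[v]]
    if (length(ch) > 0L)
      ages[v] <- max(ages[ch] + ifelse(is.na(sp$length[ch]), 0,
                                       sp$length[ch]))
  }
  lapply(seq_len(n), function(i) {
    set.seed(gene_seed(seed, i))
    sim_one_gene(sp, k, ages)
  })
}

sim_one_gene <- function(sp, k, ages) {
  acc <- new.env(parent = emptyenv())
  acc$parent <- integer(0); acc$children <- list()
  acc$label <- character(0); acc$age <- numeric(0)
  add <- function(lab, age, kids = integer(0)) {
    id <- length(acc$parent) + 1L
    acc$parent[id] <- NA_integer_
    acc$children[[id]] <- kids
    acc$label[id] <- lab
    acc$age[id] <- age
    for (c in kids) acc$parent[c] <- id
    id
  }
  # lineages per species node: list of gene-node ids; each carries its age
  coalesce <- function(lin, t0, t1) {
    while (length(lin) > 1L) {
      rate <- length(lin) * (length(lin) - 1L) / 2
      t0 <- t0 + stats::rexp(1L, rate)
      if (t0 > t1) break
      pair <- sample.int(length(lin), 2L)
      joined <- add(NA_character_, t0, kids = lin[pair])
      lin <- c(lin[-pair], joined)
    }
    lin
  }
  run <- function(v) {
    ch <- sp$children[[v]]
    lin <- if (length(ch) == 0L) {
      vapply(seq_len(k), function(j) add(sp$label[v], 0), integer(1))
    } else {
      unlist(lapply(ch, run))
    }
    blen <- sp$length[v]
    if (is.na(blen)) blen <- 0
    if (is.na(sp$parent[v])) {
      coalesce(lin, ages[v], Inf)
    } else {
      coalesce(lin, ages[v], ages[sp$parent[v]])
    }
  }
  top <- run(sp$root)
  root <- if (length(top) == 1L) top[1] else add(NA_character_, Inf, top)
  # branch lengths from ages (root branch has none)
  len <- rep(NA_real_, length(acc$parent))
  for (v in seq_along(acc$parent)) {
    p <- acc$parent[v]
    if (!is.na(p) && is.finite(acc$age[p]))
      len[v] <- acc$age[p] - acc$age[v]
  }
  multree(acc$parent, acc$children, acc$label, len, root)
}

#' Random rooted NNI perturbation
#'
#' Applies k rooted nearest-neighbor-interchange moves chosen uniformly
#' among all (internal edge, child, sibling) swaps. Stands in for gene tree
#' estimation error: the leaf multiset is unchanged and the tree stays
#' binary.
#'
#' @param tree a binary `multree` with at least 4 leaves (when k > 0).
#' @param k number of moves (0 = identity).
#' @param seed integer seed.
#' @return A perturbed `multree`.
#' @export
perturb_nni <- function(tree, k, seed) {
  stopifnot(k >= 0)
  if (k == 0L) return(tree)
  set.seed(as.integer(seed %% 2147483647))
  for (step in seq_len(k)) {
    moves <- list()
    for (v in which(lengths(tree$children) > 0L)) {
      u <- tree$parent[v]
      if (is.na(u)) next
      sibs <- setdiff(tree$children[[u]], v)
      for (s in sibs)
        for (c in tree$children[[v]])
          moves[[length(moves) + 1L]] <- c(u = u, v = v, s = s, c = c)
    }
    if (length(moves) == 0L)
      stop("tree too small for NNI")
    mv <- moves[[sample.int(length(moves), 1L)]]
    chu <- tree$children[[mv["u"]]]
    chv <- tree$children[[mv["v"]]]
    chu[match(mv["s"], chu)] <- mv["c"]
    chv[match(mv["c"], chv)] <- mv["s"]
    tree$children[[mv["u"]]] <- chu
    tree$children[[mv["v"]]] <- chv
    tree$parent[mv["c"]] <- mv["u"]
    tree$parent[mv["s"]] <- mv["v"]
    tree$length[c(mv["c"], mv["s"])] <- NA_real_
  }
  tree
}

## --------------------------------------------------------------- presets --

preset_enewick <- function(name) {
  switch(name,
    D = paste0("((((A:1,(B:1)#H1:1)n2:1,(#H1:1,C:1)n3:1)n1:1,D:1)n0:1,",
               "O:1)r;"),
    E = paste0("((((A:1,(B:1)#H1:1)a1:1,(#H1:1,C:1)a2:1)a3:1,",
               "(D:1)#H2:1)x1:1,(#H2:1,O:1)x2:1)r;"),
    F = paste0("(((A:1,(B:1)#H1:1)p1:1,((#H1:1,(C:1)#H3:1)p2:1,",
               "(#H3:1,(D:1)#H2:1)p3:1)p4:1)p5:1,(#H2:1,O:1)p6:1)r;"),
    J = paste0("(((((((a:1,(b:1)#H1:1)q1:1,(#H1:1,c:1)q2:1)q3:1,",
               "((d:1,(e:1)#H2:1)q4:1,(#H2:1,f:1)q5:1)q6:1)q7:1,",
               "((g:1)#H3:1,h:1)q8:1)q9:1,(#H3:1,i:1)q10:1)q11:1,",
               "j:1)q12:1,(k:1,(l:1,m:1)q13:1)q14:1)r;"),
    stop("unknown preset '", name, "'; options: D, E, F, J"))
}

#' ILS level to branch-length scale factor
#'
#' The simulation scenarios scale every branch of the species phylogeny by
#' a single factor chosen once from the closed-form rooted-triplet
#' discordance (2/3)exp(-tau): low = 6 (discordance ~0), moderate = 1.5
#' (~0.15), high = 0.5 (~0.4).
#'
#' @param ils_level one of "low", "moderate", "high".
#' @return Numeric scale factor.
#' @export
ils_scale <- function(ils_level) {
  switch(ils_level, low = 6, moderate = 1.5, high = 0.5,
         stop("unknown ILS level '", ils_level,
              "'; options: low, moderate, high"))
}

#' Simulation scenario presets
#'
#' Synthetic stand-ins for the classical allopolyploid benchmark scenarios:
#' D (5 taxa, 1 reticulation), E (5 taxa, 2), F (5 taxa, 3), J (13 taxa,
#' 3). The exact published model phylogenies are not reproduced; these are
#' fixed analogue networks with the stated taxon and reticulation counts.
#' All branch lengths are the ILS scale factor (coalescent units).
#'
#' @param name "D", "E", "F" or "J".
#' @param ils_level "low", "moderate" or "high" (see [ils_scale()]).
#' @param samples_per_leaf passed to [msc_model()].
#' @return List with `network` (the ground-truth `phylonet`), `model` (the
#'   `msc_model` on its unfolded MUL-tree), `multree`, `name`, `ils_level`,
#'   `scale`.
#' @export
preset_scenario <- function(name, ils_level = "low", samples_per_leaf = 1L) {
  net <- parse_enewick(preset_enewick(name))
  sc <- ils_scale(ils_level)
  net$edge_length <- net$edge_length * sc
  mt <- unfold(net)
  list(network = net, model = msc_model(mt, samples_per_leaf),
       multree = mt, name = name, ils_level = ils_level, scale = sc)
}

## ------------------------------------------------- random test instances --

#' Random binary MUL-tree
#'
#' Joins random pairs of subtrees until one remains; uses the current RNG
#' state (call `set.seed()` first for reproducibility).
#'
#' @param L a `label_multiset` (or character vector of labels with
#'   repeats).
#' @return A binary `multree`.
#' @export
rmultree <- function(L) {
  labs <- if (inherits(L, "label_multiset")) rep(names(L), ms_strip(L))
          else as.character(L)
  n <- length(labs)
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer(0)), n)
  label <- labs
  roots <- seq_len(n)
  while (length(roots) > 1L) {
    pair <- sample.int(length(roots), 2L)
    id <- length(parent) + 1L
    parent[id] <- NA_integer_
    children[[id]] <- roots[pair]
    label[id] <- NA_character_
    parent[roots[pair]] <- id
    roots <- c(roots[-pair], id)
  }
  multree(parent, children, label, root = roots[1])
}

#' Random phylogenetic network with recoverable reticulations
#'
#' Builds a random binary tree on `n_taxa` taxa, then adds `n_ret`
#' reticulations by subdividing the parent edge of a random node and
#' attaching a second parent on a random non-descendant edge. Chained
#' reticulations (a reticulation whose child, or whose child's parent, is
#' itself a reticulation) are excluded: their unfolding produces more than
#' two identical clade copies, which strict folding necessarily re-merges
#' into a single higher-degree node, so exact fold/unfold recovery would be
#' impossible by construction.
#'
#' @param n_taxa number of taxa (labels t1, t2, ...).
#' @param n_ret number of reticulations.
#' @param max_tries attempts before giving up.
#' @return A `phylonet`.
#' @export
rnetwork <- function(n_taxa, n_ret, max_tries = 100L) {
  stopifnot(n_taxa >= 3L)
  for (try in seq_len(max_tries)) {
    tr <- rmultree(paste0("t", seq_len(n_taxa)))
    # grow an explicit edge list
    n <- length(tr$parent)
    edge <- cbind(tr$parent, seq_len(n))
    edge <- edge[!is.na(tr$parent), , drop = FALSE]
    label <- tr$label
    root <- tr$root
    is_ret <- logical(n)
    ok <- TRUE
    for (rk in seq_len(n_ret)) {
      desc_of <- function(v) {      # nodes at or below v
        out <- v; frontier <- v
        while (length(frontier) > 0L) {
          nxt <- edge[edge[, 1] %in% frontier, 2]
          frontier <- setdiff(nxt, out)
          out <- c(out, frontier)
        }
        out
      }
      indeg <- tabulate(edge[, 2], length(label))
      cand <- setdiff(which(indeg == 1L), root)
      cand <- cand[!is_ret[cand]]
      # exclude nodes whose parent is a reticulation (chained copies)
      par_of <- function(v) edge[edge[, 2] == v, 1]
      cand <- cand[vapply(cand, function(v) !any(is_ret[par_of(v)]),
                          logical(1))]
      if (length(cand) == 0L) { ok <- FALSE; break }
      c1 <- cand[sample.int(length(cand), 1L)]
      below <- desc_of(c1)
      att <- which(!(edge[, 2] %in% below) & edge[, 2] != c1)
      att <- att[!is_ret[edge[att, 2]]]     # keep reticulations unchained
      if (length(att) == 0L) { ok <- FALSE; break }
      ea <- att[sample.int(length(att), 1L)]
      r <- length(label) + 1L
      t2 <- length(label) + 2L
      label <- c(label, NA_character_, NA_character_)
      is_ret <- c(is_ret, TRUE, FALSE)
      p1 <- edge[edge[, 2] == c1, 1]
      edge[edge[, 2] == c1, 1] <- r          # r -> c1
      edge[edge[, 2] == c1, 2] <- c1
      edge <- rbind(edge, c(p1, r))          # p1 -> r
      pa <- edge[ea, 1]; ca <- edge[ea, 2]
      edge[ea, ] <- c(pa, t2)                # subdivide attachment edge
      edge <- rbind(edge, c(t2, ca), c(t2, r))
    }
    if (!ok) next
    net <- tryCatch(phylonet(edge, label, root = root),
                    error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
  stop("could not generate a valid network")
}
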