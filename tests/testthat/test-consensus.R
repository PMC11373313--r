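test_that("star construction realizes the target multiset", {
  st <- build_star(label_multiset(c(x = 2L, y = 1L)))
  tr <- mulfold:::gc_as_multree(st)
  expect_equal(unclass(leaf_multiset(tr)), c(x = 2L, y = 1L))
  expect_equal(lengths(tr$children)[tr$root], 3L)

  st1 <- build_star(label_multiset("a"))
  expect_equal(ms_size(leaf_multiset(mulfold:::gc_as_multree(st1))), 1L)
})

test_that("cluster insertion succeeds, fails and instantiates disjointly", {
  st <- build_star(label_multiset(c("x", "y", "z")))
  ok <- try_insert_cluster(st, list(cluster = label_multiset(c("x", "y")),
                                    multiplicity = 1L))
  expect_true(ok)
  tr <- mulfold:::gc_as_multree(st)
  expect_identical(assign_codes(tr)[tr$root], "((x,y),z)")

  bad <- try_insert_cluster(st, list(cluster = label_multiset(c("y", "z")),
                                     multiplicity = 1L))
  expect_false(bad)
  expect_identical(assign_codes(mulfold:::gc_as_multree(st))[tr$root],
                   "((x,y),z)")   # state unchanged on failure

  st2 <- build_star(label_multiset(c(x = 2L, y = 2L)))
  ok2 <- try_insert_cluster(st2, list(cluster = label_multiset(c("x", "y")),
                                      multiplicity = 2L))
  expect_true(ok2)
  tr2 <- mulfold:::gc_as_multree(st2)
  expect_identical(assign_codes(tr2)[tr2$root], "((x,y),(x,y))")
})

test_that("self-consensus returns the input tree exactly", {
  set.seed(71)
  for (i in 1:10) {
    lab <- sample(letters[1:4], sample(4:7, 1), replace = TRUE)
    T <- rmultree(lab)
    for (n in c(1L, 5L)) {
      out <- build_consensus(rep(list(T), n))$tree
      expect_identical(assign_codes(out)[out$root],
                       assign_codes(T)[T$root])
    }
  }
})

test_that("self-consensus reproduces the cluster census exactly", {
  # the attainable invariant even for census-ambiguous inputs: the output
  # census equals the input census record for record
  census_keys <- function(tr) sort(vapply(clusters_of_tree(tr), function(r)
    mulfold:::rec_key(r$cluster, r$multiplicity), character(1)))
  set.seed(72)
  for (i in 1:15) {
    T <- rmultree(sample(letters[1:4], sample(4:9, 1), replace = TRUE))
    out <- build_consensus(rep(list(T), 3))$tree
    expect_identical(census_keys(out), census_keys(T))
  }
})

test_that("frequency-ordered greedy insertion resolves conflicts", {
  trees <- c(rep(list(parse_newick("((a,b),c);")), 3),
             list(parse_newick("((b,c),a);")))
  out <- build_consensus(trees)$tree
  expect_identical(assign_codes(out)[out$root], "((a,b),c)")
})

test_that("output leaf multiset equals L and accepted clusters appear", {
  set.seed(73)
  for (i in 1:10) {
    trees <- random_trees(4, c("a", "a", "b", "c", "d"))
    L <- mulfold:::infer_target_multiset(trees)
    res <- build_consensus(trees)
    expect_true(mulfold:::ms_equal(leaf_multiset(res$tree), L))
    # every accepted cluster appears in the output census at >= its
    # multiplicity (refinement only adds clades)
    census <- clusters_of_tree(res$tree)
    ckey <- vapply(census, function(r) ms_key(r$cluster), character(1))
    for (a in res$accepted) {
      hit <- match(ms_key(a$cluster), ckey)
      expect_false(is.na(hit))
      expect_gte(census[[hit]]$multiplicity, a$multiplicity)
    }
    # output is binary after refinement
    expect_true(all(lengths(res$tree$children) %in% c(0L, 2L)))
  }
})

test_that("refinement picks the maximum-weight resolution", {
  star <- parse_newick("(a,b,c);")
  recs <- list(list(cluster = label_multiset(c("a", "b")),
                    multiplicity = 1L, frequency = 2L))
  out <- refine_node(star, star$root, recs)
  expect_identical(assign_codes(out)[out$root], "((a,b),c)")

  # no matching clusters: deterministic left-to-right caterpillar
  out0 <- refine_node(parse_newick("(a,b,c,d);"), 5L, list())
  expect_identical(write_newick(out0), "(a,(b,(c,d)));")
})

test_that("exhaustive refinement matches the enumeration oracle and beats greedy", {
  set.seed(79)
  for (i in 1:8) {
    d <- 5L
    labs <- letters[1:d]
    star <- parse_newick(paste0("(", paste(labs, collapse = ","), ");"))
    # random record set over subsets of the children
    recs <- lapply(1:6, function(j) {
      sz <- sample(2:(d - 1), 1)
      list(cluster = label_multiset(sample(labs, sz)),
           multiplicity = 1L, frequency = sample(1:5, 1))
    })
    wfun <- mulfold:::weight_lookup(recs, 0.65)
    achieved_weight <- function(tree) {
      v <- tree$root
      cl <- mulfold:::node_clusters(tree)
      inner <- setdiff(which(lengths(tree$children) > 0L), v)
      sum(vapply(inner, function(u) wfun(cl[[u]]), numeric(1)))
    }
    exact <- refine_node(star, star$root, recs, exhaustive_cap = 6L)
    greedy <- refine_node(star, star$root, recs, exhaustive_cap = 2L)
    oracle <- oracle_best_resolution(
      mulfold:::node_clusters(star)[star$children[[star$root]]], wfun)
    expect_equal(achieved_weight(exact), oracle, tolerance = 1e-9)
    expect_gte(achieved_weight(exact), achieved_weight(greedy) - 1e-9)
    expect_true(all(lengths(exact$children) %in% c(0L, 2L)))
    expect_true(all(lengths(greedy$children) %in% c(0L, 2L)))
  }
})
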