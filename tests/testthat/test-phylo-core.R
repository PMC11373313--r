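test_that("newick parsing handles MUL-trees, degenerate input and errors", {
  t <- parse_newick("((x,z)u,(x,y,z)v)w;")
  expect_length(mulfold:::leaves_of(t), 5L)
  expect_equal(unclass(leaf_multiset(t)), c(x = 2L, y = 1L, z = 2L))
  expect_setequal(stats::na.omit(t$label[lengths(t$children) > 0]),
                  c("u", "v", "w"))

  t1 <- parse_newick("a;")
  expect_length(t1$parent, 1L)
  expect_equal(ms_size(leaf_multiset(t1)), 1L)

  expect_error(parse_newick("((a,b);"), "offset")
  expect_error(parse_newick("(a,,b);"), "offset")
  expect_error(parse_newick("(a,(b,c)));"), "offset")
})

test_that("newick round trip is the identity on canonical text", {
  for (txt in c("(a,b,c);", "((x,z)u,(x,y,z)v)w;",
                "((a:1,b:2.5)n:0.1,c:3);", "(((a,b),c),d);")) {
    expect_identical(write_newick(parse_newick(txt)), txt)
  }
})

test_that("parse/write round trips preserve topology on random trees", {
  set.seed(101)
  for (i in 1:100) {
    tr <- rmultree(sample(letters[1:6], sample(3:8, 1), replace = TRUE))
    back <- parse_newick(write_newick(tr))
    expect_identical(assign_codes(back)[back$root],
                     assign_codes(tr)[tr$root])
  }
})

test_that("parser agrees with ape on uniquely labeled trees", {
  skip_if_not_installed("ape")
  set.seed(13)
  for (i in 1:20) {
    tr <- rmultree(paste0("t", 1:6))
    txt <- write_newick(tr)
    phy <- ape::read.tree(text = txt)
    ours <- sort(vapply(clusters_of_tree(tr), function(r)
      ms_key(r$cluster), character(1)))
    theirs <- sort(ape_cluster_census(phy))
    expect_identical(ours, theirs)
  }
})

test_that("node heights follow the recursive definition", {
  t <- parse_newick("((x,z)u,(x,y,z)v)w;")
  h <- node_heights(t)
  expect_true(all(h[mulfold:::leaves_of(t)] == 0L))
  expect_equal(h[t$root], 2L)
  expect_equal(sort(h[lengths(t$children) > 0]), c(1L, 1L, 2L))
  cat4 <- parse_newick("(((a,b),c),d);")
  expect_equal(node_heights(cat4)[cat4$root], 3L)
  # parent height exceeds each child's by at least one, with equality
  set.seed(5)
  tr <- rmultree(letters[1:7])
  h <- node_heights(tr)
  for (v in which(lengths(tr$children) > 0)) {
    expect_true(all(h[v] >= 1L + h[tr$children[[v]]]))
    expect_true(any(h[v] == 1L + h[tr$children[[v]]]))
  }
})

test_that("enewick parses, writes and reports reticulations", {
  net <- parse_enewick("((a,(b)#H1),(#H1,c));")
  expect_equal(n_reticulations(net), 1L)
  indeg <- tabulate(net$edge[, 2], length(net$label))
  r <- which(indeg == 2L)
  kid <- net$edge[net$edge[, 1] == r, 2]
  expect_identical(net$label[kid], "b")

  tree_shaped <- parse_enewick("((a,b),c);")
  expect_equal(n_reticulations(tree_shaped), 0L)

  expect_error(parse_enewick("((a,#H1),(b,c));"), "never defined")
  expect_error(parse_enewick("((a,(b)#H1),((c)#H1,d));"), "more than once")
})

test_that("enewick round trip preserves the network", {
  set.seed(23)
  for (i in 1:25) {
    N <- rnetwork(sample(3:7, 1), sample(1:3, 1))
    back <- parse_enewick(write_enewick(N))
    expect_equal(n_reticulations(back), n_reticulations(N))
    expect_equal(network_distance(back, N), 0)
  }
})

test_that("unfold matches brute-force path counting", {
  net <- parse_enewick("((a,(b)#H1),(#H1,c));")
  mt <- unfold(net)
  expect_identical(write_newick(mt), "((a,b),(b,c));")
  set.seed(31)
  for (i in 1:25) {
    N <- rnetwork(sample(3:6, 1), sample(1:3, 1))
    ms <- leaf_multiset(unfold(N))
    oracle <- oracle_path_counts(N)
    expect_equal(unclass(ms)[sort(names(oracle))],
                 as.integer(oracle[sort(names(oracle))]),
                 ignore_attr = TRUE)
  }
  # tree-shaped network unfolds to itself
  tr <- parse_newick("((a,b),(c,d));")
  expect_identical(write_newick(unfold(mulfold:::as_phylonet(tr))),
                   "((a,b),(c,d));")
})
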