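test_that("isomorphism codes canonicalize child order", {
  t <- parse_newick("(((a,b)p,x)m,((b,a)q,x)n)r;")
  codes <- assign_codes(t)
  lv <- mulfold:::leaves_of(t)
  expect_identical(codes[lv[1]], "a")
  p <- which(!is.na(t$label) & t$label == "p")
  q <- which(!is.na(t$label) & t$label == "q")
  expect_identical(codes[p], "(a,b)")
  expect_identical(codes[p], codes[q])
  m <- which(!is.na(t$label) & t$label == "m")
  n <- which(!is.na(t$label) & t$label == "n")
  expect_identical(codes[m], codes[n])

  t2 <- parse_newick("((a,(b,c))u,((a,b),c)v)r;")
  codes2 <- assign_codes(t2)
  u <- which(!is.na(t2$label) & t2$label == "u")
  v <- which(!is.na(t2$label) & t2$label == "v")
  expect_false(identical(codes2[u], codes2[v]))
})

test_that("normalized edit distance: worked values and axioms", {
  ab <- parse_newick("(a,b);"); ac <- parse_newick("(a,c);")
  expect_equal(normalized_ged(ab, ab), 0)
  expect_equal(normalized_ged(ab, ac), 1 / 18, tolerance = 1e-12)
  abc <- parse_newick("(a,(b,c));")
  d1 <- normalized_ged(ab, abc); d2 <- normalized_ged(abc, ab)
  expect_gt(d1, 0); expect_lt(d1, 1)
  expect_equal(d1, d2)
  set.seed(83)
  for (i in 1:20) {
    x <- rmultree(sample(letters[1:4], sample(2:6, 1), replace = TRUE))
    y <- rmultree(sample(letters[1:4], sample(2:6, 1), replace = TRUE))
    d <- normalized_ged(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, normalized_ged(y, x))
    expect_equal(normalized_ged(x, x), 0)
  }
})

test_that("near-isomorphism gates on equal clusters first", {
  t <- parse_newick("(((a,b,c)u),((a,b)v))r;")
  u <- which(!is.na(t$label) & t$label == "u")
  v <- which(!is.na(t$label) & t$label == "v")
  expect_false(are_near_isomorphic(t, u, v, delta = 1))

  t2 <- parse_newick("((a,(b,c))u,((a,b),c)v)r;")
  u2 <- which(!is.na(t2$label) & t2$label == "u")
  v2 <- which(!is.na(t2$label) & t2$label == "v")
  d <- normalized_ged(subtree(t2, u2), subtree(t2, v2))
  expect_identical(are_near_isomorphic(t2, u2, v2, delta = 0.3), d <= 0.3)
  expect_false(are_near_isomorphic(t2, u2, v2, delta = d - 1e-9))
  expect_true(are_near_isomorphic(t2, u2, v2, delta = d + 1e-9))

  t3 <- parse_newick("((a,b)u,(b,a)v)r;")
  u3 <- which(!is.na(t3$label) & t3$label == "u")
  v3 <- which(!is.na(t3$label) & t3$label == "v")
  expect_true(are_near_isomorphic(t3, u3, v3, delta = 0))
})

test_that("clade scores follow the doubled-multiplicity rule", {
  tr <- parse_newick("((a,b)u,c)r;")
  u <- which(!is.na(tr$label) & tr$label == "u")
  mk_map <- function(...) {
    kv <- list(...)
    stats::setNames(vapply(kv, `[[`, integer(1), 2L),
                    vapply(kv, `[[`, character(1), 1L))
  }
  key <- function(labs, m) mulfold:::rec_key(label_multiset(labs), m)
  m1 <- mk_map(list(key(c("a", "b"), 2L), 4L))
  expect_equal(compute_clade_score(tr, u, m1), 8)      # 2 * 1 * 4
  m2 <- mk_map(list(key(c("a", "b"), 1L), 7L))
  expect_equal(compute_clade_score(tr, u, m2), 7)      # fallback 1 * 7
  m3 <- mk_map(list(key(c("x", "y"), 1L), 9L))
  expect_equal(compute_clade_score(tr, u, m3), 0)
  expect_equal(compute_clade_score(tr, u, NULL), 0)
})

test_that("folding merges isomorphic clades and conserves leaf labels", {
  t <- parse_newick("((a,b),(a,b));")
  net <- fold(t, 0)
  expect_equal(n_reticulations(net), 1L)
  expect_identical(assign_codes(unfold(net))[unfold(net)$root],
                   assign_codes(t)[t$root])

  uniq <- parse_newick("((a,b),(c,d));")
  netu <- fold(uniq, 0)
  expect_equal(n_reticulations(netu), 0L)
  expect_equal(network_distance(netu, mulfold:::as_phylonet(uniq)), 0)

  # codes equal after canonicalization force a merge at height 1
  t2 <- parse_newick("((x,(a,b)),(y,(b,a)));")
  net2 <- fold(t2, 0)
  expect_equal(n_reticulations(net2), 1L)
  lvs <- mulfold:::net_leaves(net2)
  expect_identical(sort(net2$label[lvs]), c("a", "b", "x", "y"))
})

test_that("delta controls whether near-isomorphic clades merge", {
  t <- parse_newick("((x,(a,(b,c))),(y,((a,b),c)));")
  strict <- fold(t, 0)
  loose <- fold(t, 0.3)
  # delta 0: only the three leaf pairs merge; delta 0.3: one clade merge
  expect_equal(n_reticulations(strict), 3L)
  expect_equal(n_reticulations(loose), 1L)
  expect_lte(n_reticulations(loose), n_reticulations(strict))
  expect_error(fold(t, -0.1), "delta")
  expect_error(fold(t, 1.5), "delta")
})

test_that("representative selection prefers the highest clade score", {
  # two non-identical clades with equal cluster; frequencies favor (a,(b,c))
  t <- parse_newick("((x,(a,(b,c))),(y,((a,b),c)));")
  gt <- rep(list(parse_newick("((x,(a,(b,c))),(y,(a,(b,c))));")), 4)
  map <- compute_sorted_clusters(gt)$map
  net <- fold(t, 0.5, map)
  expect_equal(n_reticulations(net), 1L)
  mt <- unfold(net)
  codes <- assign_codes(mt)
  expect_true("((b,c),a)" %in% codes)      # winning shape a,(b,c) kept
  expect_false("((a,b),c)" %in% codes)
})

test_that("fold/unfold round trip recovers random networks at delta 0", {
  set.seed(89)
  for (i in 1:25) {
    N <- rnetwork(sample(4:8, 1), sample(1:3, 1))
    N2 <- fold(unfold(N), 0)
    expect_equal(network_distance(N2, N), 0)
    # structural invariants of the output
    indeg <- tabulate(N2$edge[, 2], length(N2$label))
    outdeg <- tabulate(N2$edge[, 1], length(N2$label))
    expect_true(all(outdeg[indeg >= 2L] == 1L))
    expect_length(mulfold:::topo_order(N2), length(N2$label))
  }
})

test_that("binarization rewrites high in-degree reticulations", {
  t <- parse_newick("((a,b),(a,b),(a,b));")
  net <- fold(t, 0)
  indeg <- tabulate(net$edge[, 2], length(net$label))
  expect_equal(max(indeg), 3L)
  bin <- binarize_reticulations(net)
  indeg2 <- tabulate(bin$edge[, 2], length(bin$label))
  expect_true(all(indeg2 <= 2L))
  expect_identical(ms_key(leaf_multiset(unfold(bin))),
                   ms_key(leaf_multiset(unfold(net))))
})
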