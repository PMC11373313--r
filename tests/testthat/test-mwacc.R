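rec <- function(labels, m = 1L, s = 1L) {
  list(cluster = label_multiset(labels), multiplicity = as.integer(m),
       frequency = as.integer(s))
}

test_that("approximate compatibility follows the multiset definition", {
  L <- label_multiset(c("x", "x", "y", "z", "z"))
  expect_true(approx_compatible(rec(c("x", "y")), rec(c("x", "z")), L))
  expect_true(approx_compatible(rec("x"), rec(c("x", "y")), L))

  L2 <- label_multiset(c("x", "x", "y", "y", "z", "z"))
  expect_false(approx_compatible(rec(c("x", "y"), m = 2),
                                 rec(c("y", "z"), m = 2), L2))
  expect_error(approx_compatible(rec(c("q")), rec(c("x")), L),
               "not contained")
  # symmetry of the symmetrized relation; reflexivity via containment
  set.seed(53)
  for (i in 1:50) {
    g <- random_cluster_graph()
    n <- length(g$weight)
    if (n < 2) next
    i1 <- sample(n, 1); i2 <- sample(n, 1)
    expect_identical(
      approx_compatible(g$records[[i1]], g$records[[i2]], g$L),
      approx_compatible(g$records[[i2]], g$records[[i1]], g$L))
    expect_true(approx_compatible(g$records[[i1]], g$records[[i1]], g$L))
  }
})

test_that("the one-directional reading is available and asymmetric-capable", {
  # containment branches still hold either way
  L <- label_multiset(c("x", "x", "y"))
  expect_true(approx_compatible(rec("x"), rec(c("x", "y")), L,
                                symmetric = FALSE))
})

test_that("node weights follow m * s * |C|^alpha", {
  expect_equal(node_weight(rec("a")), 1)
  expect_equal(node_weight(rec(c("a", "b", "c"), m = 2, s = 5)),
               2 * 5 * 3^0.65, tolerance = 1e-9)
  expect_equal(round(node_weight(rec(c("a", "b", "c"), m = 2, s = 5)), 2),
               20.42)
  w1 <- node_weight(rec(c("a", "b"), s = 3))
  expect_equal(node_weight(rec(c("a", "b"), s = 6)), 2 * w1)
  expect_lt(node_weight(rec(c("a", "b"))), node_weight(rec(c("a", "b", "c"))))
})

test_that("graph construction: weights, symmetry, containment cliques", {
  L <- label_multiset(c("a", "a", "b", "c"))
  nested <- list(rec("a"), rec(c("a", "b")), rec(c("a", "a", "b", "c")))
  g <- build_graph(nested, L)
  expect_true(all(g$adj[upper.tri(g$adj)]))        # chain of containments
  expect_true(isSymmetric(g$adj))
  expect_false(any(diag(g$adj)))
  # the worked pair keeps its edge inside a graph
  L2 <- label_multiset(c("x", "x", "y", "z", "z"))
  g2 <- build_graph(list(rec(c("x", "y")), rec(c("x", "z"))), L2)
  expect_true(g2$adj[1, 2])
  # records that cannot fit are dropped with a warning
  expect_warning(
    g3 <- build_graph(list(rec(c("a", "b"), m = 3), rec("a")), L),
    "dropped")
  expect_length(g3$weight, 1L)
})

test_that("solver handles the hand-worked instances", {
  empty <- suppressWarnings(
    build_graph(list(), label_multiset(c("a", "b"))))
  s <- solve_mwacc(empty)
  expect_identical(s$selected, integer(0))
  expect_equal(s$total_weight, 0)

  # 3 vertices, weights {3,2,2}, only edge joins the weight-2 pair
  g <- list(records = list(rec("a", s = 3), rec("b", s = 2),
                           rec("c", s = 2)),
            weight = c(3, 2, 2),
            adj = matrix(c(FALSE, FALSE, FALSE,
                           FALSE, FALSE, TRUE,
                           FALSE, TRUE, FALSE), 3, 3),
            group = 1:3, L = label_multiset(c("a", "b", "c")))
  class(g) <- "compat_graph"
  s <- solve_mwacc(g)
  expect_equal(s$total_weight, 4)
  expect_identical(s$selected, c(2L, 3L))
  expect_equal(solve_mwacc_bruteforce(g)$total_weight, 4)

  # one multiplicity per base cluster: (C,1) w=2 vs (C,2) w=3
  g2 <- list(records = list(rec(c("a", "b"), m = 1), rec(c("a", "b"), m = 2)),
             weight = c(2, 3),
             adj = matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2),
             group = c(1L, 1L), L = label_multiset(c("a", "a", "b", "b")))
  class(g2) <- "compat_graph"
  expect_equal(solve_mwacc(g2)$total_weight, 3)
  expect_identical(solve_mwacc(g2)$selected, 2L)
  expect_equal(solve_mwacc_bruteforce(g2)$total_weight, 3)

  # single vertex; edgeless graph picks the best single vertex
  g3 <- g; g3$adj[] <- FALSE
  expect_identical(solve_mwacc_bruteforce(g3)$selected, 1L)
  expect_error(solve_mwacc_bruteforce(
    list(records = vector("list", 21), weight = numeric(21),
         adj = matrix(FALSE, 21, 21), group = 1:21)), "capped")
})

test_that("solver selections are valid independent of the solver", {
  set.seed(61)
  for (i in 1:30) {
    g <- random_cluster_graph()
    s <- solve_mwacc(g)
    expect_true(mwacc_solution_valid(g, s))
    expect_equal(s$total_weight, sum(g$weight[s$selected]))
  }
})
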