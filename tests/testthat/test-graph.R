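test_that("d-separation matches the connection-type catalog", {
  collider <- bn_structure(list(integer(0), integer(0), c(1L, 2L)))
  expect_true(d_separated(collider, 1L, 2L))
  expect_false(d_separated(collider, 1L, 2L, 3L))
  serial <- bn_structure(list(integer(0), 1L, 2L))
  expect_false(d_separated(serial, 1L, 3L))
  expect_true(d_separated(serial, 1L, 3L, 2L))
  diverge <- bn_structure(list(2L, integer(0), 2L))
  expect_true(d_separated(diverge, 1L, 3L, 2L))
  disconnected <- bn_structure(list(integer(0), integer(0), integer(0)))
  expect_true(d_separated(disconnected, 1L, 2L))
  expect_true(d_separated(disconnected, 1L, 2L, 3L))
  # conditioning on a collider's descendant also unblocks
  desc <- bn_structure(list(integer(0), integer(0), c(1L, 2L), 3L))
  expect_false(d_separated(desc, 1L, 2L, 4L))
  expect_error(d_separated(collider, 1L, 1L), "differ")
  expect_error(d_separated(collider, 1L, 3L, 3L), "not be in z")
})

test_that("d-separation agrees with the path-enumeration oracle", {
  # exhaustively on all 3-node DAGs, all pairs, all conditioning sets
  for (dag in enumerate_all_dags(3L)) {
    g <- bn_structure(dag)
    for (x in 1:2) for (y in (x + 1L):3L) {
      rest <- setdiff(1:3, c(x, y))
      for (z in list(integer(0), rest)) {
        expect_identical(d_separated(g, x, y, z),
                         dsep_path_oracle(g, x, y, z))
        expect_identical(d_separated(g, y, x, z),
                         d_separated(g, x, y, z))  # symmetry
      }
    }
  }
  # randomized 5-node DAGs with all conditioning subsets
  for (seed in 1:25) {
    g <- random_dag(5L, 0.45, seed = seed)
    x <- ((seed - 1L) %% 4L) + 1L
    y <- 5L
    rest <- setdiff(1:5, c(x, y))
    subsets <- list(integer(0))
    for (v in rest) subsets <- c(subsets, lapply(subsets, c, v))
    for (z in subsets)
      expect_identical(d_separated(g, x, y, z),
                       dsep_path_oracle(g, x, y, z))
  }
})

test_that("Markov blankets collect parents, children and spouses", {
  nb <- bn_structure(list(integer(0), 1L, 1L, 1L), class_index = 1L)
  expect_equal(markov_blanket(nb, 1L), c(2L, 3L, 4L))
  collider <- bn_structure(list(integer(0), c(1L, 3L), integer(0)))
  expect_equal(markov_blanket(collider, 1L), c(2L, 3L))
  iso <- bn_structure(list(integer(0), integer(0)))
  expect_equal(markov_blanket(iso, 1L), integer(0))
})

test_that("Markov equivalence is skeleton + v-structures", {
  chain <- bn_structure(list(integer(0), 1L, 2L))
  rev_chain <- bn_structure(list(2L, 3L, integer(0)))
  collider <- bn_structure(list(integer(0), integer(0), c(1L, 2L)))
  expect_true(markov_equivalent(chain, rev_chain))
  expect_false(markov_equivalent(chain, collider))
  expect_true(markov_equivalent(collider, collider))
  expect_error(markov_equivalent(chain, bn_structure(list(integer(0)))),
               "mismatched")
})

test_that("equivalent DAGs share all d-separation statements", {
  dags <- enumerate_all_dags(3L)
  gs <- lapply(dags, bn_structure)
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i >= j || !markov_equivalent(gs[[i]], gs[[j]])) next
    for (x in 1:2) for (y in (x + 1L):3L) {
      rest <- setdiff(1:3, c(x, y))
      for (z in list(integer(0), rest))
        expect_identical(d_separated(gs[[i]], x, y, z),
                         d_separated(gs[[j]], x, y, z))
    }
  }
})

test_that("CPDAG conversion labels compelled and reversible edges", {
  collider <- bn_structure(list(integer(0), integer(0), c(1L, 2L)))
  p <- to_cpdag(collider)
  expect_equal(p$amat, rbind(c(0L, 0L, 1L), c(0L, 0L, 1L), c(0L, 0L, 0L)))
  chain <- bn_structure(list(integer(0), 1L, 2L))
  p2 <- to_cpdag(chain)
  expect_equal(p2$amat, rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L)))
  single <- to_cpdag(bn_structure(list(integer(0))))
  expect_true(all(single$amat == 0L))
})

test_that("CPDAGs agree with the exhaustive-orientation oracle", {
  for (seed in 1:30) {
    g <- random_dag(4L + (seed %% 2L), 0.5, seed = seed + 40L)
    expect_equal(to_cpdag(g)$amat, cpdag_exhaustive_oracle(g))
  }
})

test_that("two DAGs map to the same pattern iff Markov equivalent", {
  gs <- lapply(enumerate_all_dags(3L), bn_structure)
  pat <- vapply(gs, function(g)
    paste(anbc:::pattern_status(to_cpdag(g)), collapse = ""), character(1))
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i >= j) next
    expect_identical(pat[i] == pat[j], markov_equivalent(gs[[i]], gs[[j]]))
  }
})

test_that("SHD counts pattern-level pair mismatches", {
  chain <- bn_structure(list(integer(0), 1L, 2L))
  collider <- bn_structure(list(integer(0), c(1L, 3L), integer(0)))
  expect_equal(shd(chain, chain), 0L)
  expect_equal(shd(chain, collider), 2L)
  empty <- bn_structure(list(integer(0), integer(0), integer(0)))
  one_edge <- bn_structure(list(integer(0), 1L, integer(0)))
  expect_equal(shd(empty, one_edge), 1L)
  # zero iff Markov equivalent, over random pairs
  for (seed in 1:20) {
    g1 <- random_dag(4L, 0.5, seed = seed)
    g2 <- random_dag(4L, 0.5, seed = seed + 1000L)
    expect_identical(shd(g1, g2) == 0L, markov_equivalent(g1, g2))
  }
  # raw-DAG variant distinguishes orientation within a class
  rev_chain <- bn_structure(list(2L, 3L, integer(0)))
  expect_equal(shd(chain, rev_chain), 0L)
  expect_equal(shd(chain, rev_chain, on = "dag"), 2L)
})

test_that("ANB constraint checking", {
  ds_names <- c("X0", "X1", "X2")
  anb <- bn_structure(list(integer(0), 1L, c(1L, 2L)), names = ds_names,
                      class_index = 1L)
  expect_true(is_anb_structure(anb))
  not_anb <- bn_structure(list(integer(0), 1L, 2L), names = ds_names,
                          class_index = 1L)
  expect_false(is_anb_structure(not_anb))
  class_with_parent <- bn_structure(list(2L, integer(0), c(1L, 2L)),
                                    names = ds_names, class_index = 1L)
  expect_false(is_anb_structure(class_with_parent))
})
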