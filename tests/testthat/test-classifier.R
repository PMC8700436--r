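test_that("EAP estimates follow the posterior-mean formula", {
  # binary child with one binary parent: N'_ijk = 1/4, N'_ij = 1/2;
  # N_ijk = 2 of N_j = 3 -> 2.25 / 3.5
  ds <- anb_dataset(matrix(c(1, 1, 1, 2,
                             1, 1, 2, 1), ncol = 2,
                           dimnames = list(NULL, c("X0", "X1"))),
                    class_var = 1L)
  m <- fit_eap(ds, bn_structure(list(integer(0), 1L), names = ds$vars,
                                class_index = 1L))
  expect_equal(m$cpts[[2]][1, 1], 2.25 / 3.5)
  # all counts zero -> uniform
  ds0 <- anb_dataset(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("X0", "X1"))),
                     class_var = 1L,
                     states = list(X0 = c("1", "2"), X1 = c("1", "2", "3")))
  m0 <- fit_eap(ds0, bn_structure(list(integer(0), 1L), names = ds0$vars,
                                  class_index = 1L))
  expect_equal(m0$cpts[[2]], matrix(1 / 3, nrow = 2, ncol = 3))
  # row sums are exactly one for every CPT
  for (cpt in m$cpts) expect_equal(rowSums(cpt), rep(1, nrow(cpt)))
})

test_that("class posteriors implement the Markov-blanket product rule", {
  st <- bn_structure(list(integer(0), 1L), names = c("X0", "X1"),
                     class_index = 1L)
  mod <- bn_model(st, list(matrix(c(0.5, 0.5), 1, 2),
                           matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2)),
                  states = list(X0 = c("1", "2"), X1 = c("1", "2")))
  expect_equal(unname(class_posterior(mod, c(NA, 1L))), c(0.75, 0.25))
  # fully symmetric CPTs -> uniform posterior
  sym <- bn_model(st, list(matrix(c(0.5, 0.5), 1, 2),
                           matrix(0.5, 2, 2)),
                  states = list(X0 = c("1", "2"), X1 = c("1", "2")))
  expect_equal(unname(class_posterior(sym, c(NA, 2L))), c(0.5, 0.5))
  # posteriors normalize to 1
  expect_equal(sum(class_posterior(mod, c(NA, 2L))), 1, tolerance = 1e-12)
})

test_that("variables outside the Markov blanket never change the posterior", {
  net <- random_discrete_network(5L, max_parents = 1L, seed = 4L,
                                 anb_like = FALSE)
  ds <- forward_sample(net, 400L, seed = 5L)
  # pick a structure where X1 is isolated from the class X0
  st <- bn_structure(list(integer(0), integer(0), 1L, 1L, 3L),
                     names = ds$vars, class_index = 1L)
  m <- fit_eap(ds, st)
  mb <- markov_blanket(st, 1L)
  expect_false(2L %in% mb)
  x_a <- c(NA, 1L, 2L, 1L, 1L)
  x_b <- c(NA, 2L, 2L, 1L, 1L)  # only the non-blanket slot differs
  expect_equal(class_posterior(m, x_a), class_posterior(m, x_b))
  # ... and a missing blanket variable is an error
  x_bad <- c(NA, 1L, NA, 1L, 1L)
  expect_error(class_posterior(m, x_bad), "Markov-blanket")
})

test_that("prediction takes the argmax with lowest-index ties", {
  st <- bn_structure(list(integer(0), 1L), names = c("X0", "X1"),
                     class_index = 1L)
  mod <- bn_model(st, list(matrix(c(0.5, 0.5), 1, 2),
                           matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2)),
                  states = list(X0 = c("a", "b"), X1 = c("1", "2")))
  nd <- data.frame(X1 = c("1", "2"))
  expect_equal(predict(mod, nd), c("a", "b"))
  # exact tie -> first class state
  sym <- bn_model(st, list(matrix(c(0.5, 0.5), 1, 2), matrix(0.5, 2, 2)),
                  states = list(X0 = c("a", "b"), X1 = c("1", "2")))
  expect_equal(predict(sym, nd), c("a", "a"))
  # class-only structure predicts the prior argmax
  st0 <- bn_structure(list(integer(0)), names = "X0", class_index = 1L)
  prior <- bn_model(st0, list(matrix(c(0.3, 0.7), 1, 2)),
                    states = list(X0 = c("a", "b")))
  expect_equal(predict(prior, data.frame(row.names = 1:3)), rep("b", 3))
})

test_that("naive Bayes structure is the all-children ANB", {
  ds <- random_dataset(10L, c(2L, 2L, 3L, 2L), seed = 6L)
  nb <- naive_bayes_structure(ds)
  expect_identical(nb$parents, list(integer(0), 1L, 1L, 1L))
  expect_true(is_anb_structure(nb))
  expect_equal(markov_blanket(nb, 1L), 2:4)
})

test_that("Markov-equivalent ANB structures are classification-equivalent", {
  # EAP with the score-coherent prior makes the one-step posterior
  # predictive invariant across Markov-equivalent DAGs, so class posteriors
  # must agree exactly; exhaustively over all ANB structures on 3 binary
  # features x all feature configurations
  ds <- random_dataset(60L, c(2L, 2L, 2L, 2L), seed = 17L)
  feature_dags <- enumerate_all_dags(3L)
  structures <- lapply(feature_dags, function(dag) {
    bn_structure(c(list(integer(0)),
                   lapply(dag, function(p) sort(c(1L, p + 1L)))),
                 names = ds$vars, class_index = 1L)
  })
  models <- lapply(structures, function(st) fit_eap(ds, st))
  configs <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  post <- lapply(models, function(m)
    t(apply(configs, 1L, function(cf)
      class_posterior(m, c(NA_integer_, cf)))))
  for (i in seq_along(structures)) for (j in seq_along(structures)) {
    if (i >= j) next
    if (markov_equivalent(structures[[i]], structures[[j]]))
      expect_equal(post[[i]], post[[j]], tolerance = 1e-9)
  }
})

test_that("EAP estimates converge to the sampling distribution", {
  net <- random_discrete_network(4L, max_parents = 2L, seed = 8L,
                                 anb_like = TRUE)
  ds <- forward_sample(net, 1e5, seed = 9L)
  m <- fit_eap(ds, net$structure)
  expect_lt(max(abs(unlist(m$cpts) - unlist(net$cpts))), 0.01)
})
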