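test_that("forward sampling respects degenerate CPTs and seeds", {
  st <- bn_structure(list(integer(0), 1L), names = c("X0", "X1"),
                     class_index = 1L)
  det <- bn_model(st, list(matrix(c(1, 0), 1, 2),
                           matrix(c(0, 1, 1, 0), 2, 2)),
                  states = list(X0 = c("1", "2"), X1 = c("1", "2")))
  ds <- forward_sample(det, 10L, seed = 1L)
  expect_true(all(ds$x[, 1] == 1L))
  expect_true(all(ds$x[, 2] == 2L))       # P(X1 = 2 | X0 = 1) = 1
  expect_equal(nrow(forward_sample(det, 0L, seed = 1L)$x), 0L)
  net <- random_discrete_network(4L, seed = 2L, anb_like = TRUE)
  expect_identical(forward_sample(net, 50L, seed = 3L)$x,
                   forward_sample(net, 50L, seed = 3L)$x)
})

test_that("sampled frequencies concentrate around the CPT entries", {
  st <- bn_structure(list(integer(0)), names = "X0", class_index = 1L)
  m <- bn_model(st, list(matrix(c(0.3, 0.7), 1, 2)),
                states = list(X0 = c("1", "2")))
  ds <- forward_sample(m, 10000L, seed = 5L)
  expect_lt(abs(mean(ds$x[, 1] == 1L) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("random networks are reproducible and honor their constraints", {
  n1 <- random_discrete_network(5L, max_parents = 2L, seed = 21L,
                                anb_like = TRUE)
  n2 <- random_discrete_network(5L, max_parents = 2L, seed = 21L,
                                anb_like = TRUE)
  expect_identical(n1$structure$parents, n2$structure$parents)
  expect_equal(n1$cpts, n2$cpts)
  expect_true(is_anb_structure(n1$structure))
  expect_true(all(lengths(lapply(n1$structure$parents, setdiff, 1L)) <= 2L))
  flat <- random_discrete_network(4L, max_parents = 0L, seed = 22L)
  expect_equal(sum(lengths(flat$structure$parents)), 0L)
  # CPT rows are proper distributions with the configured floor
  for (cpt in n1$cpts) {
    expect_equal(rowSums(cpt), rep(1, nrow(cpt)))
    expect_true(all(cpt >= 0.049))
  }
})

test_that("class-posterior KLD is a weighted divergence with hand value", {
  net <- random_discrete_network(4L, seed = 23L, anb_like = TRUE)
  ds <- forward_sample(net, 2000L, seed = 24L)
  m <- fit_eap(ds, net$structure)
  expect_equal(class_posterior_kld(m, m, net), 0)
  # single-configuration hand value: one binary feature forced to state 1,
  # posteriors [0.75, 0.25] vs [0.5, 0.5]
  st <- bn_structure(list(integer(0), 1L), names = c("X0", "X1"),
                     class_index = 1L)
  mk <- function(p1) bn_model(st, list(matrix(c(0.5, 0.5), 1, 2),
                                       matrix(c(p1, 1 - p1,
                                                1 - p1, p1), 2,
                                              byrow = TRUE)),
                              states = list(X0 = c("1", "2"),
                                            X1 = c("1", "2")))
  # reference with X1 degenerate at state 1 puts all weight on that config
  ref <- bn_model(st, list(matrix(c(0.5, 0.5), 1, 2),
                           matrix(c(1, 0, 1, 0), 2, byrow = TRUE)),
                  states = list(X0 = c("1", "2"), X1 = c("1", "2")))
  model_b <- mk(0.75)  # posterior [0.75, 0.25] at X1 = 1
  model_a <- mk(0.5)   # posterior [0.5, 0.5]
  expect_equal(class_posterior_kld(model_a, model_b, ref),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
})

test_that("reference ANB of a naive-Bayes-shaped network is naive Bayes", {
  ds <- random_dataset(500L, c(2L, 2L, 2L), seed = 25L)
  nb <- naive_bayes_structure(ds)
  nbm <- fit_eap(ds, nb)
  ref <- reference_optimal_anb(nbm)
  expect_identical(ref$parents, nb$parents)
  expect_true(is_anb_structure(ref))
})

test_that("reference ANB keeps a genuine feature-feature dependence", {
  # X0 -> X1 -> X2 with X0 -> X2: dropping the X1 -> X2 edge breaks the
  # I-map property, so the population-optimal ANB must contain it
  st <- bn_structure(list(integer(0), 1L, c(1L, 2L)),
                     names = c("X0", "X1", "X2"), class_index = 1L)
  states <- list(X0 = c("1", "2"), X1 = c("1", "2"), X2 = c("1", "2"))
  cpts <- list(matrix(c(0.5, 0.5), 1, 2),
               matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
               matrix(c(0.85, 0.15, 0.3, 0.7,
                        0.6, 0.4, 0.1, 0.9), 4, byrow = TRUE))
  net <- bn_model(st, cpts, states)
  ref <- reference_optimal_anb(net)
  expect_true(2L %in% ref$parents[[3]] || 3L %in% ref$parents[[2]])
  expect_true(is_anb_structure(ref))
})

test_that("the asymptotic protocol returns a tidy report", {
  net <- random_discrete_network(4L, seed = 26L, anb_like = TRUE)
  ev <- asymptotic_eval(net, c(100L, 5000L), seed = 27L)
  expect_equal(ev$n, c(100L, 5000L))
  expect_true(all(ev$shd >= 0))
  expect_true(all(ev$kld >= -1e-12))
  empty <- asymptotic_eval(net, integer(0), seed = 27L)
  expect_equal(nrow(empty), 0L)
})

test_that("cross-validation folds are balanced and scored correctly", {
  ds <- random_dataset(23L, c(2L, 2L), seed = 28L)
  # single-class data: every method is always right
  one_class <- anb_dataset(cbind(X0 = rep(1L, 10), X1 = rep(1:2, 5)),
                           class_var = "X0",
                           states = list(X0 = c("1", "2"),
                                         X1 = c("1", "2")))
  expect_equal(cross_validate_accuracy(one_class, "nb", folds = 5L,
                                       seed = 1L), 1)
  expect_error(cross_validate_accuracy(ds, "nb", folds = 24L), "folds")
  # a decisive binary feature makes naive Bayes near-perfect
  big <- withr::with_seed(29L, {
    x0 <- sample(1:2, 400, TRUE)
    anb_dataset(cbind(X0 = x0,
                      X1 = ifelse(stats::runif(400) < 0.98, x0, 3L - x0)),
                class_var = "X0",
                states = list(X0 = c("1", "2"), X1 = c("1", "2")))
  })
  expect_gte(cross_validate_accuracy(big, "nb", folds = 10L, seed = 30L),
             0.95)
})
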