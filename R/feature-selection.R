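#' Zero-order Bayes-factor feature selection
#'
#' Runs exactly one marginal-independence Bayes-factor test per feature:
#' `log BF(X0, Xi | empty)`. A feature is removed when the factor exceeds the
#' threshold (`log BF > log(delta)`, evidence for independence from the
#' class) and kept otherwise. Only zero-order tests are performed -- they are
#' more reliable than higher-order ones and keep the cost at n evaluations.
#' Raising `delta` makes removal harder, so the kept set at a larger `delta`
#' is a superset of the kept set at a smaller one (the log factors are fixed;
#' only the cutoff moves).
#'
#' @param dataset an [anb_dataset] with a designated class.
#' @param ess equivalent sample size N' of the underlying BDeu scores.
#' @param delta Bayes-factor threshold (> 0).
#' @return object of class `anb_selection`: `kept` and `removed` feature
#'   indices, `log_bf` (named per feature), `ess`, `delta`.
#' @export
bf_pc_select <- function(dataset, ess = 1, delta = 20) {
  if (delta <= 0) stop("delta must be positive")
  c0 <- dataset$class_index
  feats <- setdiff(seq_along(dataset$vars), c0)
  log_bf <- vapply(feats, function(i)
    log_bayes_factor(dataset, c0, i, integer(), ess = ess), numeric(1))
  names(log_bf) <- dataset$vars[feats]
  removed <- feats[log_bf > log(delta)]
  structure(
    list(kept = setdiff(feats, removed), removed = removed,
         log_bf = log_bf, ess = ess, delta = delta),
    class = "anb_selection")
}

#' @export
print.anb_selection <- function(x, ...) {
  cat(sprintf("anb_selection (ess = %g, delta = %g): %d kept, %d removed\n",
              x$ess, x$delta, length(x$kept), length(x$removed)))
  print(round(x$log_bf, 4))
  invisible(x)
}

# One (select -> exact ANB learn -> EAP fit) pass on a training split.
fit_selected_anb <- function(train, ess, delta, max_vars = 25L) {
  sel <- bf_pc_select(train, ess = ess, delta = delta)
  c0 <- train$class_index
  sub <- dataset_subset(train, sort(c(c0, sel$kept)))
  if (length(sel$kept) == 0L) {
    g <- bn_structure(list(integer(0)), names = sub$vars, class_index = 1L)
  } else {
    g <- learn_exact(sub, mode = "anb", ess = ess, max_vars = max_vars)
  }
  list(model = fit_eap(sub, g), selection = sel)
}

accuracy_on <- function(model, test) {
  pred <- predict(model, test, type = "class")
  truth <- test$states[[test$class_index]][test$x[, test$class_index]]
  mean(pred == truth)
}

#' Tune (N', delta) by two-fold cross-validation
#'
#' For every grid point the full pipeline (Bayes-factor selection, exact ANB
#' search, EAP fit) is trained on each half of a seeded unstratified split
#' and scored on the other half; the grid point with the highest mean
#' accuracy wins. Ties break toward the smaller N', then the smaller delta
#' (weaker prior, more inclusive selection).
#'
#' @param dataset an [anb_dataset] (N >= 2).
#' @param ess_grid candidate equivalent sample sizes.
#' @param delta_grid candidate Bayes-factor thresholds.
#' @param seed integer seed for the split.
#' @return list with `ess`, `delta`, and the full `grid` of mean accuracies.
#' @export
tune_hyperparameters <- function(dataset, ess_grid = c(1, 2, 5),
                                 delta_grid = c(3, 20, 150), seed = 1L) {
  n <- nrow(dataset$x)
  if (n < 2L) stop("degenerate dataset: need at least two rows")
  if (!length(ess_grid) || !length(delta_grid)) stop("empty tuning grid")
  if (any(delta_grid <= 0)) stop("delta must be positive")
  ess_grid <- sort(unique(ess_grid))
  delta_grid <- sort(unique(delta_grid))
  perm <- with_seed(seed, sample.int(n))
  half <- list(perm[seq_len(n %/% 2)], perm[(n %/% 2 + 1L):n])
  grid <- expand.grid(delta = delta_grid, ess = ess_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("ess", "delta")]
  grid$accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    acc <- numeric(2)
    for (f in 1:2) {
      train <- dataset_rows(dataset, half[[f]])
      test <- dataset_rows(dataset, half[[3L - f]])
      fit <- fit_selected_anb(train, ess = grid$ess[gi],
                              delta = grid$delta[gi])
      acc[f] <- accuracy_on(fit$model, test)
    }
    grid$accuracy[gi] <- mean(acc)
  }
  best <- which.max(grid$accuracy)  # grid ordered (ess asc, delta asc):
  list(ess = grid$ess[best], delta = grid$delta[best], grid = grid)
}

#' The fsANB-BDeu pipeline
#'
#' Tunes (N', delta) by two-fold cross-validation, selects features with the
#' zero-order Bayes-factor test at the chosen point, learns the exact ANB
#' over the class plus the kept features, and fits EAP parameters. When every
#' feature is removed the classifier degenerates to the class marginal
#' (prediction by prior) -- the only total behavior when the Markov blanket
#' is empty.
#'
#' @param dataset an [anb_dataset].
#' @param ess_grid,delta_grid tuning grids.
#' @param seed integer seed (tuning split).
#' @param tune set `FALSE` to skip tuning and use the first grid values.
#' @param max_vars exact-search cap applied after selection.
#' @return list with `model` (a [bn_model] over the class + kept features),
#'   `selection` (an `anb_selection` on the full variable indexing), `ess`,
#'   `delta`.
#' @export
fit_fsanb <- function(dataset, ess_grid = c(1, 2, 5),
                      delta_grid = c(3, 20, 150), seed = 1L, tune = TRUE,
                      max_vars = 25L) {
  if (tune && nrow(dataset$x) >= 2L) {
    tuned <- tune_hyperparameters(dataset, ess_grid, delta_grid, seed = seed)
  } else {
    tuned <- list(ess = ess_grid[1L], delta = delta_grid[1L])
  }
  fit <- fit_selected_anb(dataset, ess = tuned$ess, delta = tuned$delta,
                          max_vars = max_vars)
  list(model = fit$model, selection = fit$selection,
       ess = tuned$ess, delta = tuned$delta)
}
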