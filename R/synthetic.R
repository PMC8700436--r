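# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Ancestral (forward) sampling from a network
#'
#' Samples `n` i.i.d. rows by drawing each variable in topological order from
#' its CPT row given the already-sampled parent configuration. Deterministic
#' given `seed`.
#'
#' @param network a [bn_model].
#' @param n number of rows (>= 0).
#' @param seed integer seed.
#' @return an [anb_dataset] (class designation inherited from the network).
#' @export
forward_sample <- function(network, n, seed = 1L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  g <- network$structure
  p <- g$n_vars
  x <- matrix(NA_integer_, nrow = n, ncol = p,
              dimnames = list(NULL, g$names))
  if (n > 0L) {
    with_seed(seed, {
      for (i in topological_order(g)) {
        cpt <- network$cpts[[i]]
        r <- ncol(cpt)
        j <- parent_config_index(x, g$parents[[i]],
                                 network$cardinalities)
        cum <- cpt %*% upper.tri(diag(r), diag = TRUE)
        u <- stats::runif(n)
        x[, i] <- 1L + as.integer(rowSums(u > cum[j, , drop = FALSE]))
      }
    })
  }
  anb_dataset(x, class_var = if (is.na(g$class_index)) 1L else g$class_index,
              states = network$states)
}

#' Random discrete network fixtures
#'
#' Draws a random DAG (uniform topological order, parent sets bounded by
#' `max_parents`) with CPT rows sampled from a symmetric Dirichlet(0.5),
#' whose U-shaped density yields the decisive conditional probabilities
#' typical of benchmark networks. With `anb_like = TRUE` the first variable
#' is a parentless class adjacent to every feature, so the network satisfies
#' the assumptions under which exact ANB learning recovers the
#' classification-equivalent structure (all features in the class's Markov
#' blanket, all blanket members adjacent to the class).
#'
#' @param n_vars total number of variables (>= 2).
#' @param max_parents parent bound for the randomized edges.
#' @param cardinalities integer vector (recycled) of state counts.
#' @param seed integer seed.
#' @param anb_like force the ANB shape described above.
#' @param alpha Dirichlet concentration for CPT rows.
#' @param effect_margin minimum total-variation distance required between CPT
#'   rows that differ in a single parent's state (maximized over the other
#'   parents' states). A positive margin guarantees every edge carries
#'   detectable dependence, so the network is faithful to its DAG with a
#'   quantified margin rather than only almost surely; CPTs are redrawn until
#'   the margin holds.
#' @param min_prob floor on every CPT entry (keeps the distribution strictly
#'   positive so no branch of the state space is starved of data).
#' @return a [bn_model] (class index 1 when `anb_like`).
#' @export
random_discrete_network <- function(n_vars, max_parents = 2L,
                                    cardinalities = 2L, seed = 1L,
                                    anb_like = FALSE, alpha = 0.5,
                                    effect_margin = 0.2, min_prob = 0.05) {
  n_vars <- as.integer(n_vars)
  if (n_vars < 2L) stop("need at least two variables")
  if (max_parents < 0L) stop("infeasible parent bound")
  cardinalities <- rep_len(as.integer(cardinalities), n_vars)
  with_seed(seed, {
    ord <- if (anb_like) c(1L, 1L + sample.int(n_vars - 1L))
           else sample.int(n_vars)
    parents <- rep(list(integer(0)), n_vars)
    for (pos in seq_len(n_vars)[-1L]) {
      v <- ord[pos]
      preds <- ord[seq_len(pos - 1L)]
      if (anb_like) preds <- setdiff(preds, 1L)
      k <- sample.int(min(max_parents, length(preds)) + 1L, 1L) - 1L
      pa <- if (k > 0L) preds[sample.int(length(preds), k)] else integer(0)
      if (anb_like && v != 1L) pa <- c(1L, pa)
      parents[[v]] <- sort(pa)
    }
    states <- lapply(cardinalities, function(r) paste0("s", seq_len(r)))
    names(states) <- paste0("X", seq_len(n_vars) - 1L)
    cpts <- lapply(seq_len(n_vars), function(i)
      draw_cpt(parents[[i]], cardinalities[i], cardinalities, alpha,
               effect_margin, min_prob))
    st <- bn_structure(parents, names = names(states),
                       class_index = if (anb_like) 1L else NA_integer_)
    bn_model(st, cpts, states)
  })
}

# Draw one CPT, redrawing until every parent shows an effect of at least
# `margin` (total variation between two rows differing only in that parent)
# and every entry clears `min_prob`.
draw_cpt <- function(parents, r, cardinalities, alpha, margin, min_prob) {
  q <- as.integer(prod(as.numeric(cardinalities[parents])))
  grid <- parent_config_grid(parents, cardinalities)
  for (attempt in seq_len(1000L)) {
    m <- matrix(stats::rgamma(q * r, shape = alpha), nrow = q)
    # reserve min_prob per state, spread the rest by the Dirichlet draw:
    # every entry is >= min_prob exactly and rows sum to 1
    m <- min_prob + (1 - r * min_prob) * m / rowSums(m)
    ok <- TRUE
    for (t in seq_along(parents)) {
      others <- grid[, -t, drop = FALSE]
      key <- apply(others, 1L, paste, collapse = ",")
      eff <- 0
      for (k in unique(key)) {
        rows <- which(key == k)
        if (length(rows) < 2L) next
        for (a in seq_len(length(rows) - 1L)) for (b in (a + 1L):length(rows))
          eff <- max(eff, sum(abs(m[rows[a], ] - m[rows[b], ])) / 2)
      }
      if (eff < margin) { ok <- FALSE; break }
    }
    if (ok) return(m)
  }
  stop("could not draw a CPT meeting the effect margin")
}

# Exact joint distribution of a model: configs (nconf x p matrix of state
# indices, enumerated with the LAST variable fastest) and their
# probabilities. Guarded against blow-up.
joint_table <- function(model, max_configs = 2^20) {
  g <- model$structure
  p <- g$n_vars
  nconf <- prod(as.numeric(model$cardinalities))
  if (nconf > max_configs)
    stop("configuration space too large to enumerate (", nconf, " > ",
         max_configs, ")")
  configs <- parent_config_grid(seq_len(p), model$cardinalities)
  logp <- numeric(nrow(configs))
  for (i in seq_len(p)) {
    j <- parent_config_index(configs, g$parents[[i]], model$cardinalities)
    logp <- logp + log(model$cpts[[i]][cbind(j, configs[, i])])
  }
  list(configs = configs, p = exp(logp))
}

#' Kullback-Leibler divergence between class posteriors
#'
#' `sum_x P_ref(x) sum_c P_b(c|x) log[P_b(c|x) / P_a(c|x)]` where `x` ranges
#' over every feature configuration, `P_ref(x)` is the exact feature marginal
#' of the reference (generative) network, `model_b` is the true-structure
#' model and `model_a` the learned one. Feature configurations are enumerated
#' exactly; spaces above 2^20 configurations are rejected.
#'
#' @param model_a,model_b [bn_model]s over the reference's variable set
#'   (same names and states).
#' @param reference a [bn_model] providing the joint weighting and the class
#'   designation.
#' @return non-negative KLD (0 iff the two posteriors agree everywhere with
#'   positive reference weight).
#' @export
class_posterior_kld <- function(model_a, model_b, reference) {
  g <- reference$structure
  c0 <- g$class_index
  if (is.na(c0)) stop("reference has no designated class variable")
  for (m in list(model_a, model_b))
    if (!identical(m$structure$names, g$names))
      stop("models must share the reference's variable set")
  jt <- joint_table(reference)
  feats <- setdiff(seq_len(g$n_vars), c0)
  # collapse the joint over the class slot to weight feature configurations
  key <- parent_config_index(jt$configs, feats, reference$cardinalities)
  w <- as.numeric(rowsum(jt$p, key))
  feat_grid <- parent_config_grid(feats, reference$cardinalities)
  total <- 0
  for (jj in seq_len(nrow(feat_grid))) {
    if (w[jj] <= 0) next
    x <- rep(NA_integer_, g$n_vars)
    x[feats] <- feat_grid[jj, ]
    pa <- class_posterior(model_a, x)
    pb <- class_posterior(model_b, x)
    nz <- pb > 0
    total <- total + w[jj] * sum(pb[nz] * (log(pb[nz]) - log(pa[nz])))
  }
  total
}

#' Population-optimal ANB structure of a network
#'
#' The I-map with the fewest parameters among all ANB structures, obtained by
#' running the exact ANB search on expected counts: fractional counts
#' `N_ref * P(Xi = k, Z = j)` under the network's exact joint distribution
#' (the log-Gamma score accepts real counts). Sampling noise is thereby
#' removed from the reference; `N_ref` defaults to 1e6.
#'
#' @param network a [bn_model] with a class designation.
#' @param ess equivalent sample size for the score.
#' @param n_ref pseudo sample size scaling the expected counts.
#' @param max_vars size guard.
#' @return a [bn_structure] satisfying the ANB constraint.
#' @export
reference_optimal_anb <- function(network, ess = 1, n_ref = 1e6,
                                  max_vars = 12L) {
  g <- network$structure
  if (is.na(g$class_index)) stop("network has no designated class variable")
  if (g$n_vars > max_vars) stop("network too large for the exact reference")
  jt <- joint_table(network)
  card <- network$cardinalities
  local_fun <- function(i, parents) {
    q <- as.integer(prod(as.numeric(card[parents])))
    j <- parent_config_index(jt$configs, parents, card)
    k <- jt$configs[, i]
    counts <- matrix(0, nrow = q, ncol = card[i])
    idx <- j + q * (k - 1L)
    acc <- rowsum(jt$p, idx)
    counts[as.integer(rownames(acc))] <- acc * n_ref
    bdeu_score_counts(counts, ess)
  }
  res <- exact_search_core(g$n_vars, g$class_index, "anb", local_fun)
  bn_structure(res$parents, names = g$names, class_index = g$class_index)
}

#' Asymptotic SHD/KLD evaluation protocol
#'
#' For each sample size: draw a dataset from the generative network, learn
#' the ANB structure exactly, fit EAP parameters, then report (a) the SHD
#' between the learned structure and the population-optimal ANB of the
#' network and (b) the class-posterior KLD between the learned model and the
#' true structure fitted by EAP on the same sample. On networks whose class
#' variable's Markov blanket covers all features (with blanket members
#' adjacent to the class) both quantities reach 0 as the sample grows; on
#' networks violating those assumptions the KLD may plateau above 0.
#'
#' @param network a [bn_model] with class designation.
#' @param sizes integer vector of sample sizes.
#' @param seed integer seed (one sub-seed per size is derived from it).
#' @param ess equivalent sample size for learning.
#' @return data.frame with columns `n`, `shd`, `kld`, `score`.
#' @export
asymptotic_eval <- function(network, sizes, seed = 1L, ess = 1) {
  sizes <- as.integer(sizes)
  ref <- if (length(sizes)) reference_optimal_anb(network, ess = ess)
         else NULL
  out <- data.frame(n = integer(0), shd = integer(0), kld = numeric(0),
                    score = numeric(0))
  true_struct <- network$structure
  for (t in seq_along(sizes)) {
    n <- sizes[t]
    ds <- forward_sample(network, n, seed = seed + t - 1L)
    learned <- learn_exact(ds, mode = "anb", ess = ess)
    model <- fit_eap(ds, learned)
    model_true <- fit_eap(ds, true_struct)
    out <- rbind(out, data.frame(
      n = n,
      shd = shd(learned, ref),
      kld = class_posterior_kld(model, model_true, network),
      score = attr(learned, "score")))
  }
  out
}

#' k-fold cross-validated classification accuracy
#'
#' Rows are shuffled with the seed, split into near-equal folds (sizes differ
#' by at most one), and each fold is scored by a model trained on the rest.
#'
#' @param dataset an [anb_dataset].
#' @param method `"nb"` (naive Bayes), `"gbn"`, `"anb"` (exact search), or
#'   `"fsanb"` (Bayes-factor selection + exact ANB, hyperparameters tuned by
#'   internal two-fold CV on each training split).
#' @param folds number of folds (2 <= folds <= N).
#' @param seed integer seed for the shuffle (and the nested tuning).
#' @param ess equivalent sample size for scoring/fitting (non-fsanb methods).
#' @return mean accuracy in [0, 1].
#' @export
cross_validate_accuracy <- function(dataset,
                                    method = c("nb", "anb", "gbn", "fsanb"),
                                    folds = 10L, seed = 1L, ess = 1) {
  method <- match.arg(method)
  n <- nrow(dataset$x)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  if (folds > n) stop("more folds than rows")
  perm <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep(seq_len(folds), length.out = n)  # round-robin: sizes differ by <= 1
  correct <- 0L
  for (f in seq_len(folds)) {
    train <- dataset_rows(dataset, which(fold_id != f))
    test <- dataset_rows(dataset, which(fold_id == f))
    model <- switch(method,
      nb = fit_eap(train, naive_bayes_structure(train)),
      anb = fit_eap(train, learn_exact(train, "anb", ess = ess)),
      gbn = fit_eap(train, learn_exact(train, "gbn", ess = ess)),
      fsanb = fit_fsanb(train, seed = seed + f)$model)
    pred <- predict(model, test, type = "class")
    truth <- dataset$states[[dataset$class_index]][test$x[, test$class_index]]
    correct <- correct + sum(pred == truth)
  }
  correct / n
}

# Row subset preserving the full state space (so fold datasets keep the
# global encoding even when a state is absent from the split).
dataset_rows <- function(dataset, idx) {
  anb_dataset(dataset$x[idx, , drop = FALSE],
              class_var = dataset$class_index, states = dataset$states)
}
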