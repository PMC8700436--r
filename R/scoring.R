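#' BDeu scoring
#'
#' The Bayesian Dirichlet equivalent uniform (BDeu) marginal likelihood with
#' equivalent sample size `ess` (N'). Dirichlet hyperparameters are
#' `N'/(r_i q)` per cell and `N'/q` per parent configuration, which makes the
#' score equal across Markov-equivalent DAGs. All scores are natural logs.
#'
#' @name bdeu
NULL

# Core: log BDeu local score from a numeric q x r count matrix. Counts may be
# fractional (expected counts); lgamma accepts real arguments.
bdeu_score_counts <- function(counts, ess) {
  if (ess <= 0) stop("ess must be positive")
  q <- nrow(counts); r <- ncol(counts)
  aj <- ess / q
  ajk <- ess / (r * q)
  nj <- rowSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

#' Local BDeu score of a conditional frequency table
#'
#' Computes
#' `sum_j [lnG(N'/q) - lnG(N'/q + N_j)] + sum_jk [lnG(N'/(rq) + N_jk) - lnG(N'/(rq))]`
#' in double precision. An all-zero table scores exactly 0.
#'
#' @param table an `anb_cft` from [build_cft()] (or a bare q x r count matrix).
#' @param ess equivalent sample size N' > 0 (default 1, the standard choice
#'   that lets the data dominate the posterior).
#' @return log marginal likelihood contribution of this child/parent pair.
#' @export
bdeu_local_score <- function(table, ess = 1) {
  counts <- if (inherits(table, "anb_cft")) table$counts else as.matrix(table)
  bdeu_score_counts(counts, ess)
}

#' Network BDeu score
#'
#' Decomposable: the sum over variables of the local score of each variable
#' given its parent set.
#'
#' @param dataset an [anb_dataset].
#' @param dag a [bn_structure] over the dataset's variables.
#' @param ess equivalent sample size N'.
#' @param cache optional environment used to memoize local scores across calls
#'   (keyed by child and parent set; create with `new.env()`).
#' @return log BDeu score of the network.
#' @export
network_bdeu_score <- function(dataset, dag, ess = 1, cache = NULL) {
  if (dag$n_vars != length(dataset$vars))
    stop("structure and dataset variable counts differ")
  total <- 0
  for (i in seq_len(dag$n_vars)) {
    pa <- dag$parents[[i]]
    if (!is.null(cache)) {
      key <- paste0("s", i, "|", paste(pa, collapse = ","), "|", ess)
      if (!is.null(cache[[key]])) {
        total <- total + cache[[key]]
        next
      }
      val <- bdeu_score_counts(build_cft(dataset, i, pa)$counts, ess)
      cache[[key]] <- val
      total <- total + val
    } else {
      total <- total + bdeu_score_counts(build_cft(dataset, i, pa)$counts, ess)
    }
  }
  total
}

#' Log Bayes factor for conditional independence
#'
#' `log BF(X, Y | Z) = Score(CFT(X, Z)) - Score(CFT(X, Z union {Y}))`, the log
#' ratio of the marginal likelihoods of the local model without and with `y`
#' as an extra parent of `x`. Positive values favor independence; the decision
#' rule declares X and Y independent given Z when `BF > delta`, i.e.
#' `log BF > log(delta)`.
#'
#' @param dataset an [anb_dataset].
#' @param x,y distinct variable indices, neither in `z`.
#' @param z conditioning set (default empty: the zero-order test).
#' @param ess equivalent sample size N'.
#' @return log Bayes factor (natural log).
#' @export
log_bayes_factor <- function(dataset, x, y, z = integer(), ess = 1) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("x and y must not appear in z")
  bdeu_score_counts(build_cft(dataset, x, z)$counts, ess) -
    bdeu_score_counts(build_cft(dataset, x, c(z, y))$counts, ess)
}
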