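#' Exact structure search by dynamic programming over variable subsets
#'
#' Finds a globally BDeu-optimal DAG. In `gbn` mode the search space is all
#' DAGs over the variables. In `anb` mode it is the augmented-naive-Bayes
#' space: the class variable `X0` is parentless and is a parent of every
#' feature, with feature-feature edges free. Since `Score_0(empty)` is
#' constant over ANB structures, the DP drops it and adds it back for
#' reporting.
#'
#' The algorithm has three table-building phases: (1) local scores
#' `Score_i(Z)` for every admissible (variable, candidate parent set) pair;
#' (2) best parents `g_i*(Pi(Z))`, the admissible subset of each available
#' set maximizing the local score; (3) best sinks via the recursion
#' `score(Z) = max_s [ Score_s(g_s*(Pi(Z \ s))) + score(Z \ s) ]`, using the
#' fact that every DAG has a childless variable (sink). Tables are built
#' bottom-up over subsets in order of increasing cardinality.
#'
#' Ties are broken deterministically: among equal-scoring parent candidates
#' the smaller set wins, then the lower bit-set encoding; among equal-scoring
#' sinks the lowest variable index wins.
#'
#' @param dataset an [anb_dataset].
#' @param mode `"anb"` or `"gbn"`.
#' @param ess equivalent sample size N' of the BDeu score.
#' @param max_vars guard on the total variable count (tables are O(n 2^n)).
#' @return a [bn_structure] carrying attributes `score` (the full-network log
#'   BDeu score, class term included) and `work_counts` (instrumented
#'   iteration counts of the three phases).
#' @export
learn_exact <- function(dataset, mode = c("anb", "gbn"), ess = 1,
                        max_vars = 25L) {
  mode <- match.arg(mode)
  p <- length(dataset$vars)
  if (p > max_vars)
    stop("variable count ", p, " exceeds the exact-search cap ", max_vars)
  if (mode == "anb" && is.na(dataset$class_index))
    stop("anb mode requires a designated class variable")
  local_fun <- function(i, parents)
    bdeu_score_counts(build_cft(dataset, i, parents)$counts, ess)
  res <- exact_search_core(p, dataset$class_index, mode, local_fun)
  g <- bn_structure(res$parents, names = dataset$vars,
                    class_index = dataset$class_index)
  score <- res$score
  if (mode == "anb")
    score <- score + local_fun(dataset$class_index, integer(0))
  attr(g, "score") <- score
  attr(g, "work_counts") <- res$work_counts
  g
}

# DP engine shared by data-driven and expected-count search. `local_fun(i,
# parents)` returns the local score of variable i with the given parent
# indices (in anb mode the class variable is always passed as part of
# `parents` for features and never searched itself).
exact_search_core <- function(n_vars, class_index, mode, local_fun) {
  searched <- if (mode == "anb") setdiff(seq_len(n_vars), class_index)
              else seq_len(n_vars)
  m <- length(searched)
  if (m < 1L) stop("nothing to search")
  if (m > 30L) stop("subset space too large")
  nmask <- bitwShiftL(1L, m)
  bit <- bitwShiftL(1L, seq_len(m) - 1L)
  popcount <- integer(nmask)
  for (s in seq_len(nmask - 1L))
    popcount[s + 1L] <- popcount[bitwAnd(s, s - 1L) + 1L] + 1L
  mask_vars <- function(mask) searched[bitwAnd(mask, bit) != 0L]
  by_size <- order(popcount)  # masks (0-based: by_size - 1) by cardinality

  # Phase 1: local scores ls[[b]][mask+1] for mask not containing bit b.
  n_local <- 0L
  ls <- vector("list", m)
  for (b in seq_len(m)) {
    v <- rep(NA_real_, nmask)
    for (mask in 0:(nmask - 1L)) {
      if (bitwAnd(mask, bit[b]) != 0L) next
      pa <- mask_vars(mask)
      if (mode == "anb") pa <- sort(c(class_index, pa))
      v[mask + 1L] <- local_fun(searched[b], pa)
      n_local <- n_local + 1L
    }
    ls[[b]] <- v
  }

  # Phase 2: best parents over every available set. bp_set stores the chosen
  # parent mask (over searched variables; the class is implicit in anb mode).
  n_bp <- 0L
  bp_score <- vector("list", m)
  bp_set <- vector("list", m)
  for (b in seq_len(m)) {
    sc <- rep(NA_real_, nmask)
    st <- rep(NA_integer_, nmask)
    for (idx in by_size) {
      mask <- idx - 1L
      if (bitwAnd(mask, bit[b]) != 0L) next
      best_s <- ls[[b]][mask + 1L]
      best_m <- mask
      if (mask != 0L) {
        for (x in seq_len(m)) {
          if (bitwAnd(mask, bit[x]) == 0L) next
          sub <- bitwAnd(mask, bitwNot(bit[x]))
          cs <- sc[sub + 1L]; cm <- st[sub + 1L]
          if (cs > best_s ||
              (cs == best_s && (popcount[cm + 1L] < popcount[best_m + 1L] ||
                                (popcount[cm + 1L] == popcount[best_m + 1L] &&
                                 cm < best_m)))) {
            best_s <- cs; best_m <- cm
          }
        }
      }
      sc[mask + 1L] <- best_s
      st[mask + 1L] <- best_m
      n_bp <- n_bp + 1L
    }
    bp_score[[b]] <- sc
    bp_set[[b]] <- st
  }

  # Phase 3: best sink per subset (Eq. (8)-style recursion).
  n_sink <- 0L
  net_score <- rep(NA_real_, nmask)
  sink <- rep(NA_integer_, nmask)
  net_score[1L] <- 0
  for (idx in by_size) {
    mask <- idx - 1L
    if (mask == 0L) next
    best_s <- -Inf
    best_b <- NA_integer_
    for (b in seq_len(m)) {          # ascending index = deterministic ties
      if (bitwAnd(mask, bit[b]) == 0L) next
      rest <- bitwAnd(mask, bitwNot(bit[b]))
      cand <- bp_score[[b]][rest + 1L] + net_score[rest + 1L]
      if (cand > best_s) { best_s <- cand; best_b <- b }
    }
    net_score[mask + 1L] <- best_s
    sink[mask + 1L] <- best_b
    n_sink <- n_sink + 1L
  }

  # Reconstruct the optimal DAG by peeling sinks off the full set.
  parents <- rep(list(integer(0)), n_vars)
  mask <- nmask - 1L
  while (mask != 0L) {
    b <- sink[mask + 1L]
    rest <- bitwAnd(mask, bitwNot(bit[b]))
    pm <- bp_set[[b]][rest + 1L]
    pa <- mask_vars(pm)
    if (mode == "anb") pa <- sort(c(class_index, pa))
    parents[[searched[b]]] <- pa
    mask <- rest
  }
  list(parents = parents, score = net_score[nmask],
       work_counts = c(local = n_local, best_parents = n_bp, sinks = n_sink))
}

#' Iteration counts of the exact-search phases
#'
#' Returns the number of table entries the three DP phases build for a
#' problem with `n_features` feature variables plus one class variable, in
#' each mode. These are the counts [learn_exact()] instruments at run time;
#' the ANB-constrained search performs strictly fewer iterations than the
#' unconstrained search on the same variable set.
#'
#' @param n_features number of feature variables (>= 1).
#' @param mode `"anb"` or `"gbn"`.
#' @return named numeric vector `(local, best_parents, sinks)`.
#' @export
dp_work_counts <- function(n_features, mode = c("anb", "gbn")) {
  mode <- match.arg(mode)
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("need at least one feature")
  m <- if (mode == "anb") n_features else n_features + 1L
  # one entry per (searched variable, subset of the others) in phases 1-2;
  # one per non-empty subset of the searched variables in phase 3
  c(local = m * 2^(m - 1),
    best_parents = m * 2^(m - 1),
    sinks = 2^m - 1)
}

# All permutations of a vector (n! grows fast; callers keep n <= 5).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

all_subsets <- function(v) {
  out <- list(integer(0))
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out
}

#' Brute-force search oracle
#'
#' Independent of the DP: scores every admissible DAG and returns an argmax.
#' For four or fewer searched variables every parent-set combination is
#' enumerated literally and checked for acyclicity; for five, every
#' topological order is enumerated with every subset of each variable's
#' predecessors (every DAG appears under at least one of its orders, so the
#' maximum is exact). Intended as a test oracle; sizes are capped.
#'
#' @param dataset an [anb_dataset].
#' @param mode `"anb"` or `"gbn"`.
#' @param ess equivalent sample size N'.
#' @return list with `structure` (a [bn_structure]) and `score` (full-network
#'   log BDeu, class term included in anb mode).
#' @export
brute_force_optimum <- function(dataset, mode = c("anb", "gbn"), ess = 1) {
  mode <- match.arg(mode)
  p <- length(dataset$vars)
  searched <- if (mode == "anb") setdiff(seq_len(p), dataset$class_index)
              else seq_len(p)
  m <- length(searched)
  if (m > 5L) stop("brute force capped at 5 searched variables")
  local_fun <- function(i, parents)
    bdeu_score_counts(build_cft(dataset, i, parents)$counts, ess)
  with_class <- function(pa) {
    if (mode == "anb") sort(c(dataset$class_index, pa)) else sort(pa)
  }
  # direct (non-recursive) local-score lookup over searched-parent subsets
  subsets <- all_subsets(seq_len(m))
  sub_key <- vapply(subsets, function(s) paste(s, collapse = ","),
                    character(1))
  ls <- matrix(NA_real_, nrow = m, ncol = length(subsets))
  for (b in seq_len(m)) for (si in seq_along(subsets)) {
    s <- subsets[[si]]
    if (b %in% s) next
    ls[b, si] <- local_fun(searched[b], with_class(searched[s]))
  }
  score_of <- function(b, s) ls[b, match(paste(sort(s), collapse = ","),
                                         sub_key)]
  best_score <- -Inf
  best_parents <- NULL
  consider <- function(par_positions, total) {
    if (total > best_score) {
      best_score <<- total
      best_parents <<- par_positions
    }
  }
  if (m <= 4L) {
    # every parent-set combination, acyclicity checked by Kahn's algorithm
    choices <- lapply(seq_len(m), function(b)
      Filter(function(s) !(b %in% s), subsets))
    recurse <- function(b, acc, total) {
      if (b > m) {
        if (!is.null(topological_order(acc))) consider(acc, total)
        return(invisible(NULL))
      }
      for (s in choices[[b]])
        recurse(b + 1L, c(acc, list(s)), total + score_of(b, s))
    }
    recurse(1L, list(), 0)
  } else {
    for (ord in all_permutations(seq_len(m))) {
      total <- 0
      acc <- vector("list", m)
      ok <- TRUE
      for (pos in seq_along(ord)) {
        b <- ord[pos]
        preds <- if (pos == 1L) integer(0) else ord[seq_len(pos - 1L)]
        best_b <- -Inf; best_set <- NULL
        for (s in all_subsets(preds)) {
          v <- score_of(b, s)
          if (v > best_b) { best_b <- v; best_set <- s }
        }
        acc[[b]] <- sort(best_set)
        total <- total + best_b
      }
      if (ok) consider(acc, total)
    }
  }
  parents <- rep(list(integer(0)), p)
  for (b in seq_len(m))
    parents[[searched[b]]] <- with_class(searched[best_parents[[b]]])
  score <- best_score
  if (mode == "anb")
    score <- score + local_fun(dataset$class_index, integer(0))
  list(structure = bn_structure(parents, names = dataset$vars,
                                class_index = dataset$class_index),
       score = score)
}
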