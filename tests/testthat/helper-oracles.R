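# Independent oracles and fixture builders shared across the suite. These
# deliberately use brute-force formulations (path enumeration, literal DAG
# enumeration, sequential predictive products) so they share no code path
# with the implementations they check.

# -- datasets ---------------------------------------------------------------

# Random discrete dataset with given cardinalities; column 1 is the class.
random_dataset <- function(n_rows, cardinalities, seed) {
  withr::with_seed(seed, {
    x <- sapply(seq_along(cardinalities), function(i)
      sample.int(cardinalities[i], n_rows, replace = TRUE))
    if (!is.matrix(x)) x <- matrix(x, nrow = n_rows)
  })
  states <- lapply(cardinalities, function(r) as.character(seq_len(r)))
  names(states) <- paste0("X", seq_along(cardinalities) - 1L)
  anb_dataset(x, class_var = 1L, states = states)
}

# The 4-row two-variable fixture used for the worked score values.
fixture4 <- function() {
  anb_dataset(matrix(c(1, 1, 2, 1,
                       1, 2, 1, 1), ncol = 2,
                     dimnames = list(NULL, c("X0", "X1"))),
              class_var = "X0")
}

# -- sequential Dirichlet-multinomial predictive oracle ---------------------

# exp(local BDeu score) equals the product over rows of the posterior
# predictive probability of each observation given the rows before it.
predictive_log_score <- function(child_states, parent_configs, q, r, ess) {
  a_jk <- ess / (r * q)
  a_j <- ess / q
  njk <- matrix(0, nrow = q, ncol = r)
  nj <- rep(0, q)
  logp <- 0
  for (d in seq_along(child_states)) {
    j <- parent_configs[d]; k <- child_states[d]
    logp <- logp + log((a_jk + njk[j, k]) / (a_j + nj[j]))
    njk[j, k] <- njk[j, k] + 1
    nj[j] <- nj[j] + 1
  }
  logp
}

# -- graph oracles ----------------------------------------------------------

# d-separation by explicit enumeration of all simple paths in the skeleton.
dsep_path_oracle <- function(g, x, y, z) {
  adj <- matrix(FALSE, g$n_vars, g$n_vars)
  for (i in seq_len(g$n_vars)) adj[g$parents[[i]], i] <- TRUE
  und <- adj | t(adj)
  desc <- lapply(seq_len(g$n_vars), function(v) {
    # v plus all descendants
    out <- v; todo <- v
    while (length(todo)) {
      w <- todo[1L]; todo <- todo[-1L]
      ch <- which(adj[w, ] & !(seq_len(g$n_vars) %in% out))
      out <- c(out, ch); todo <- c(todo, ch)
    }
    out
  })
  active_path <- function(path) {
    if (length(path) > 2L) {
      for (t in 2:(length(path) - 1L)) {
        v <- path[t]
        into_v <- adj[path[t - 1L], v] && adj[path[t + 1L], v]
        if (into_v) {
          if (!any(desc[[v]] %in% z)) return(FALSE)   # blocked collider
        } else {
          if (v %in% z) return(FALSE)                  # blocked non-collider
        }
      }
    }
    TRUE
  }
  found_active <- FALSE
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      if (active_path(path)) found_active <<- TRUE
      return(invisible(NULL))
    }
    for (w in which(und[v, ])) {
      if (w %in% path || found_active) next
      dfs(c(path, w))
    }
  }
  dfs(x)
  !found_active
}

# All DAGs over n nodes (literal parent-set product + acyclicity filter).
enumerate_all_dags <- function(n) {
  subsets <- list(integer(0))
  for (v in seq_len(n)) subsets <- c(subsets, lapply(subsets, c, v))
  out <- list()
  recurse <- function(i, acc) {
    if (i > n) {
      if (!is.null(topological_order(acc))) out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (s in subsets) {
      if (i %in% s) next
      recurse(i + 1L, c(acc, list(s)))
    }
  }
  recurse(1L, list())
  out
}

# Random DAG as a bn_structure.
random_dag <- function(n, p_edge, seed, class_index = NA_integer_) {
  withr::with_seed(seed, {
    ord <- sample.int(n)
    parents <- rep(list(integer(0)), n)
    for (pos in 2:n) {
      preds <- ord[seq_len(pos - 1L)]
      keep <- preds[stats::runif(length(preds)) < p_edge]
      parents[[ord[pos]]] <- sort(keep)
    }
    bn_structure(parents, class_index = class_index)
  })
}

# CPDAG oracle: enumerate every orientation of the skeleton, keep acyclic
# DAGs with identical v-structures; an edge is compelled iff oriented the
# same way in every member of the class.
cpdag_exhaustive_oracle <- function(g) {
  n <- g$n_vars
  edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  skel <- edges[apply(edges, 1L, function(e)
    e[1] %in% g$parents[[e[2]]] || e[2] %in% g$parents[[e[1]]]), ,
    drop = FALSE]
  ne <- nrow(skel)
  vref <- anbc:::v_structures(g)
  members <- list()
  if (ne > 0L) {
    for (mask in 0:(2^ne - 1L)) {
      parents <- rep(list(integer(0)), n)
      for (e in seq_len(ne)) {
        a <- skel[e, 1L]; b <- skel[e, 2L]
        if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) != 0L)
          parents[[a]] <- c(parents[[a]], b)   # b -> a
        else
          parents[[b]] <- c(parents[[b]], a)   # a -> b
      }
      if (is.null(topological_order(parents))) next
      cand <- bn_structure(parents)
      if (identical(anbc:::v_structures(cand), vref))
        members[[length(members) + 1L]] <- cand
    }
  }
  amat <- matrix(0L, n, n)
  for (e in seq_len(ne)) {
    a <- skel[e, 1L]; b <- skel[e, 2L]
    ab <- all(vapply(members, function(m) a %in% m$parents[[b]], logical(1)))
    ba <- all(vapply(members, function(m) b %in% m$parents[[a]], logical(1)))
    if (ab) amat[a, b] <- 1L
    else if (ba) amat[b, a] <- 1L
    else { amat[a, b] <- 1L; amat[b, a] <- 1L }
  }
  amat
}

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "anbc")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}
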