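#' DAG structures
#'
#' A `bn_structure` is a directed acyclic graph stored as a parent-set map:
#' `parents[[i]]` is the (possibly empty) sorted vector of parent indices of
#' variable i. Acyclicity is verified at construction by topological sort.
#'
#' @param parents list of integer vectors, one per variable.
#' @param names optional variable names.
#' @param class_index optional index of the designated class variable `X0`.
#' @return object of class `bn_structure`.
#' @export
bn_structure <- function(parents, names = NULL, class_index = NA_integer_) {
  n <- length(parents)
  parents <- lapply(parents, function(p) sort(as.integer(p)))
  for (i in seq_len(n)) {
    p <- parents[[i]]
    if (any(p < 1L) || any(p > n)) stop("parent index out of range")
    if (i %in% p) stop("self-loop at variable ", i)
    if (anyDuplicated(p)) stop("duplicated parent")
  }
  if (is.null(names)) names <- paste0("X", seq_len(n) - 1L)
  g <- structure(list(n_vars = n, parents = parents, names = names,
                      class_index = as.integer(class_index)),
                 class = "bn_structure")
  if (is.null(topological_order(g))) stop("structure is cyclic")
  g
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("bn_structure: %d variables, %d edges\n",
              x$n_vars, sum(lengths(x$parents))))
  for (i in seq_len(x$n_vars)) {
    if (length(x$parents[[i]]))
      cat("  ", paste(x$names[x$parents[[i]]], collapse = ", "),
          " -> ", x$names[i], "\n", sep = "")
  }
  invisible(x)
}

#' Topological order of a DAG (Kahn's algorithm)
#'
#' @param g a [bn_structure] (or a bare parent-set list).
#' @return integer vector ordering parents before children, or `NULL` if the
#'   graph is cyclic.
#' @export
topological_order <- function(g) {
  parents <- if (inherits(g, "bn_structure")) g$parents else g
  n <- length(parents)
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[[i]])
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) NULL else order
}

children_of <- function(g, x) {
  which(vapply(g$parents, function(p) x %in% p, logical(1)))
}

adjacency_matrix <- function(g) {
  n <- g$n_vars
  a <- matrix(FALSE, n, n)
  for (i in seq_len(n)) a[g$parents[[i]], i] <- TRUE
  a
}

ancestors_of <- function(g, nodes) {
  todo <- as.integer(nodes)
  seen <- rep(FALSE, g$n_vars)
  seen[todo] <- TRUE
  while (length(todo)) {
    v <- todo[1L]; todo <- todo[-1L]
    for (p in g$parents[[v]]) if (!seen[p]) {
      seen[p] <- TRUE
      todo <- c(todo, p)
    }
  }
  which(seen)
}

#' d-separation
#'
#' Tests whether `x` and `y` are d-separated given the conditioning set `z`:
#' every path between them is blocked, i.e. carries a non-collider inside `z`
#' or a collider with itself and all its descendants outside `z`. Implemented
#' by moralizing the ancestral subgraph of \{x, y\} union z and checking
#' connectivity after removing `z` (sound and complete for d-separation).
#'
#' @param g a [bn_structure].
#' @param x,y distinct variable indices not in `z`.
#' @param z conditioning set (integer vector, possibly empty).
#' @return logical.
#' @export
d_separated <- function(g, x, y, z = integer()) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  n <- g$n_vars
  if (x < 1L || x > n || y < 1L || y > n || any(z < 1L) || any(z > n))
    stop("invalid variable index")
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("x and y must not be in z")
  anc <- ancestors_of(g, c(x, y, z))
  in_anc <- rep(FALSE, n); in_anc[anc] <- TRUE
  # moral graph of the ancestral subgraph
  adj <- matrix(FALSE, n, n)
  for (v in anc) {
    pv <- g$parents[[v]][in_anc[g$parents[[v]]]]
    adj[pv, v] <- TRUE; adj[v, pv] <- TRUE
    if (length(pv) > 1L) adj[pv, pv] <- TRUE   # marry parents
  }
  diag(adj) <- FALSE
  # remove conditioning nodes, test reachability x -> y
  if (length(z)) { adj[z, ] <- FALSE; adj[, z] <- FALSE }
  reach <- rep(FALSE, n); reach[x] <- TRUE
  todo <- x
  while (length(todo)) {
    v <- todo[1L]; todo <- todo[-1L]
    nb <- which(adj[v, ] & !reach)
    reach[nb] <- TRUE
    todo <- c(todo, nb)
  }
  !reach[y]
}

#' Markov blanket of a variable
#'
#' Parents, children, and parents of children (spouses) of `x`, excluding `x`.
#'
#' @param g a [bn_structure].
#' @param x variable index.
#' @return sorted integer vector.
#' @export
markov_blanket <- function(g, x) {
  x <- as.integer(x)
  if (x < 1L || x > g$n_vars) stop("invalid variable index")
  ch <- children_of(g, x)
  mb <- unique(c(g$parents[[x]], ch, unlist(g$parents[ch])))
  sort(setdiff(mb, x))
}

# v-structures as a character set "a|c|b" with a < b, a,b non-adjacent parents
# of the collider c.
v_structures <- function(g) {
  out <- character(0)
  adj <- adjacency_matrix(g)
  und <- adj | t(adj)
  for (c in seq_len(g$n_vars)) {
    pa <- g$parents[[c]]
    if (length(pa) < 2L) next
    for (ii in seq_len(length(pa) - 1L)) for (jj in (ii + 1L):length(pa)) {
      a <- pa[ii]; b <- pa[jj]
      if (!und[a, b]) out <- c(out, paste(a, c, b, sep = "|"))
    }
  }
  sort(out)
}

skeleton_pairs <- function(g) {
  adj <- adjacency_matrix(g)
  und <- adj | t(adj)
  which(und & upper.tri(und), arr.ind = TRUE)
}

#' Markov equivalence of two DAGs
#'
#' Two DAGs are Markov equivalent iff they share the same skeleton and the
#' same set of v-structures (colliders whose parents are non-adjacent).
#'
#' @param g1,g2 [bn_structure]s over the same variable set.
#' @return logical.
#' @export
markov_equivalent <- function(g1, g2) {
  if (g1$n_vars != g2$n_vars) stop("mismatched variable counts")
  s1 <- skeleton_pairs(g1); s2 <- skeleton_pairs(g2)
  if (nrow(s1) != nrow(s2)) return(FALSE)
  key <- function(s) sort(paste(s[, 1], s[, 2], sep = "-"))
  if (!identical(key(s1), key(s2))) return(FALSE)
  identical(v_structures(g1), v_structures(g2))
}

#' Completed partially directed acyclic graph (CPDAG)
#'
#' Converts a DAG to the canonical pattern of its Markov equivalence class:
#' compelled edges stay directed, reversible edges become undirected. Uses the
#' label-edges algorithm of Chickering (1995), which orders edges along a
#' topological order and propagates compelled labels.
#'
#' @param g a [bn_structure].
#' @return object of class `bn_pattern` with an `amat` matrix: `amat[i, j]`
#'   is 1 when a directed edge i -> j is present, and `amat[i, j] ==
#'   amat[j, i] == 1` encodes an undirected edge.
#' @export
to_cpdag <- function(g) {
  n <- g$n_vars
  topo <- topological_order(g)
  rank <- integer(n); rank[topo] <- seq_len(n)
  # Edge ordering: by child's topological rank, then by parent's rank
  # descending (Chickering's ordering).
  edges <- do.call(rbind, lapply(seq_len(n), function(ch) {
    pa <- g$parents[[ch]]
    if (!length(pa)) return(NULL)
    cbind(pa, ch)
  }))
  lab <- matrix(0L, n, n)  # 0 unknown, 1 compelled, -1 reversible
  if (!is.null(edges)) {
    ord <- order(rank[edges[, 2]], -rank[edges[, 1]])
    edges <- edges[ord, , drop = FALSE]
    repeat {
      un <- which(lab[edges] == 0L)
      if (!length(un)) break
      e <- edges[un[1L], ]
      x <- e[1L]; y <- e[2L]
      done <- FALSE
      for (w in g$parents[[x]]) {
        if (lab[w, x] != 1L) next
        if (!(w %in% g$parents[[y]])) {
          # every edge into y becomes compelled
          for (p in g$parents[[y]]) lab[p, y] <- 1L
          done <- TRUE
          break
        } else {
          lab[w, y] <- 1L
        }
      }
      if (done) next
      zs <- setdiff(g$parents[[y]], x)
      if (length(zs) && any(!(zs %in% g$parents[[x]]))) {
        for (p in g$parents[[y]]) if (lab[p, y] == 0L) lab[p, y] <- 1L
      } else {
        for (p in g$parents[[y]]) if (lab[p, y] == 0L) lab[p, y] <- -1L
      }
    }
  }
  amat <- matrix(0L, n, n)
  for (ch in seq_len(n)) for (pa in g$parents[[ch]]) {
    if (lab[pa, ch] == 1L) amat[pa, ch] <- 1L
    else { amat[pa, ch] <- 1L; amat[ch, pa] <- 1L }
  }
  structure(list(n_vars = n, amat = amat, names = g$names),
            class = "bn_pattern")
}

#' @export
print.bn_pattern <- function(x, ...) {
  n <- x$n_vars
  dir <- und <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (x$amat[i, j] == 1L && x$amat[j, i] == 0L)
      dir <- c(dir, paste(x$names[i], "->", x$names[j]))
    if (i < j && x$amat[i, j] == 1L && x$amat[j, i] == 1L)
      und <- c(und, paste(x$names[i], "--", x$names[j]))
  }
  cat("bn_pattern:", length(dir), "directed,", length(und),
      "undirected edges\n")
  for (e in c(dir, und)) cat("  ", e, "\n", sep = "")
  invisible(x)
}

# Pairwise edge status in a pattern: 0 none, 1 undirected, 2 i->j, 3 j->i
# (for i < j).
pattern_status <- function(p) {
  n <- p$n_vars
  if (n < 2L) return(integer(0))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  apply(pairs, 1L, function(e) {
    i <- e[1L]; j <- e[2L]
    f <- p$amat[i, j]; b <- p$amat[j, i]
    if (f == 0L && b == 0L) 0L
    else if (f == 1L && b == 1L) 1L
    else if (f == 1L) 2L else 3L
  })
}

#' Structural Hamming distance
#'
#' Both DAGs are converted to their CPDAGs; the SHD is the number of node
#' pairs whose edge status (absent / undirected / directed either way)
#' differs between the two patterns. `shd(g1, g2) == 0` iff the DAGs are
#' Markov equivalent. Set `on = "dag"` to compare the raw DAGs instead.
#'
#' @param g1,g2 [bn_structure]s over the same variable set.
#' @param on `"cpdag"` (default) or `"dag"`.
#' @return non-negative integer.
#' @export
shd <- function(g1, g2, on = c("cpdag", "dag")) {
  on <- match.arg(on)
  if (g1$n_vars != g2$n_vars) stop("mismatched variable sets")
  as_pat <- function(g) {
    if (on == "cpdag") return(to_cpdag(g))
    structure(list(n_vars = g$n_vars, amat = adjacency_matrix(g) * 1L,
                   names = g$names), class = "bn_pattern")
  }
  sum(pattern_status(as_pat(g1)) != pattern_status(as_pat(g2)))
}

#' Check the augmented-naive-Bayes constraint
#'
#' An ANB structure has a parentless class variable with an edge to every
#' feature; feature-feature edges are unrestricted.
#'
#' @param g a [bn_structure] with `class_index` set.
#' @return logical.
#' @export
is_anb_structure <- function(g) {
  c0 <- g$class_index
  if (is.na(c0)) stop("structure has no designated class variable")
  if (length(g$parents[[c0]])) return(FALSE)
  feats <- setdiff(seq_len(g$n_vars), c0)
  all(vapply(feats, function(i) c0 %in% g$parents[[i]], logical(1)))
}

#' Read / write edge-list structure files
#'
#' One `parent child` pair per line, using variable names.
#'
#' @param g a [bn_structure].
#' @param path output file.
#' @export
write_edgelist <- function(g, path) {
  lines <- character(0)
  for (i in seq_len(g$n_vars)) for (p in g$parents[[i]])
    lines <- c(lines, paste(g$names[p], g$names[i]))
  writeLines(lines, path)
  invisible(path)
}

#' @param names variable names (fixes the variable set and order; needed
#'   because isolated variables never appear in an edge list).
#' @param class_index optional class designation.
#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, names, class_index = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parents <- rep(list(integer(0)), length(names))
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) != 2L) stop("malformed edge line: ", ln)
    p <- match(tok[1L], names); c <- match(tok[2L], names)
    if (is.na(p) || is.na(c)) stop("unknown variable in edge line: ", ln)
    parents[[c]] <- c(parents[[c]], p)
  }
  bn_structure(parents, names = names, class_index = class_index)
}
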