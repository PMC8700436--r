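#' Discrete datasets for Bayesian-network classifiers
#'
#' An `anb_dataset` holds N i.i.d. rows over `n + 1` discrete variables
#' `X0, X1, ..., Xn`, one of which is designated the class variable. Cells are
#' stored as 1-based state indices; the mapping from index to the original
#' state label is kept per variable so predictions can be reported on the
#' original labels.
#'
#' @param x integer matrix (rows = instances, columns = variables) of 1-based
#'   state indices, or a data.frame of factors/characters to be encoded.
#' @param class_var name (or index) of the class variable.
#' @param states optional named list of state-label vectors; inferred from the
#'   data when omitted (labels sorted lexicographically).
#' @return an object of class `anb_dataset` with fields `x` (integer matrix),
#'   `vars` (variable names), `states` (list of label vectors),
#'   `cardinalities` (integer vector `r_i`), `class_index`.
#' @export
anb_dataset <- function(x, class_var, states = NULL) {
  if (is.data.frame(x)) {
    vars <- names(x)
    if (is.null(states)) {
      states <- lapply(x, function(col) sort(unique(as.character(col))))
      names(states) <- vars
    }
    enc <- mapply(function(col, st) {
      idx <- match(as.character(col), st)
      if (anyNA(idx)) stop("value outside declared states in column encoding")
      idx
    }, x, states[vars], SIMPLIFY = TRUE)
    x <- matrix(as.integer(enc), nrow = nrow(x),
                dimnames = list(NULL, vars))
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "integer"
    vars <- colnames(x)
    if (is.null(vars)) {
      vars <- paste0("X", seq_len(ncol(x)) - 1L)
      colnames(x) <- vars
    }
    if (is.null(states))
      states <- lapply(seq_len(ncol(x)), function(i) {
        as.character(seq_len(max(1L, if (nrow(x)) max(x[, i]) else 1L)))
      })
    names(states) <- vars
  }
  cardinalities <- vapply(states, length, integer(1))
  if (is.character(class_var)) {
    class_index <- match(class_var, vars)
    if (is.na(class_index)) stop("unknown class variable: ", class_var)
  } else {
    class_index <- as.integer(class_var)
    if (class_index < 1L || class_index > ncol(x))
      stop("class index out of range")
  }
  if (any(cardinalities < 2L))
    stop("variable(s) with a single state (cardinality < 2): ",
         paste(vars[cardinalities < 2L], collapse = ", "))
  if (nrow(x)) {
    for (i in seq_len(ncol(x))) {
      xi <- x[, i]
      if (any(is.na(xi)) || any(xi < 1L) || any(xi > cardinalities[i]))
        stop("state index out of range in column ", vars[i])
    }
  }
  structure(
    list(x = x, vars = vars, states = states,
         cardinalities = unname(cardinalities),
         class_index = class_index),
    class = "anb_dataset")
}

#' @export
print.anb_dataset <- function(x, ...) {
  cat(sprintf("anb_dataset: %d rows, %d variables (class: %s)\n",
              nrow(x$x), length(x$vars), x$vars[x$class_index]))
  cat("  cardinalities:",
      paste(sprintf("%s=%d", x$vars, x$cardinalities), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname anb_dataset
n_instances <- function(x) nrow(x$x)

#' Median binarization of a numeric column
#'
#' Continuous variables are discretized into two bins at the sample median of
#' the whole column (computed once, before any cross-validation split). Values
#' less than or equal to the cutoff map to state 1, values above it to state 2.
#'
#' @param values non-empty numeric vector.
#' @return integer vector of states in \{1, 2\}.
#' @export
discretize_median <- function(values) {
  if (length(values) == 0L) stop("empty vector")
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values must be removed before binarization")
  cutoff <- stats::median(values)
  out <- ifelse(values <= cutoff, 1L, 2L)
  if (length(unique(out)) < 2L)
    stop("constant column: median binarization would yield cardinality 1")
  out
}

#' Load a CSV dataset with the standard preprocessing
#'
#' Reads a header CSV, drops every row containing the missing marker `"?"`,
#' median-binarizes the listed continuous columns, and encodes the remaining
#' columns as categorical with states sorted lexicographically.
#'
#' @param path CSV file with a header row.
#' @param class_name name of the class variable (must appear in the header).
#' @param continuous_columns character vector of columns to median-binarize.
#' @param missing_marker string marking a missing cell; the UCI convention
#'   `"?"` by default.
#' @return an [anb_dataset].
#' @export
load_dataset <- function(path, class_name, continuous_columns = character(),
                         missing_marker = "?") {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  if (!class_name %in% names(df)) stop("unknown class_name: ", class_name)
  bad <- setdiff(continuous_columns, names(df))
  if (length(bad)) stop("unknown continuous column(s): ",
                        paste(bad, collapse = ", "))
  keep <- !Reduce(`|`, lapply(df, function(col) col == missing_marker))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty dataset after removing missing rows: ", path)
  states <- vector("list", ncol(df))
  names(states) <- names(df)
  for (nm in names(df)) {
    if (nm %in% continuous_columns) {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      if (anyNA(v)) stop("non-numeric value in continuous column ", nm)
      df[[nm]] <- as.character(discretize_median(v))
      states[[nm]] <- c("1", "2")
    } else {
      states[[nm]] <- sort(unique(df[[nm]]))
    }
  }
  anb_dataset(df, class_var = class_name, states = states)
}

#' Restrict a dataset to a subset of its variables
#'
#' @param dataset an [anb_dataset].
#' @param vars variable indices (or names) to keep; must include the class.
#' @return an [anb_dataset] over the kept variables, class re-designated.
#' @export
dataset_subset <- function(dataset, vars) {
  if (is.character(vars)) vars <- match(vars, dataset$vars)
  vars <- as.integer(vars)
  if (anyNA(vars) || any(vars < 1L) || any(vars > length(dataset$vars)))
    stop("invalid variable selection")
  if (!dataset$class_index %in% vars)
    stop("subset must include the class variable")
  anb_dataset(dataset$x[, vars, drop = FALSE],
              class_var = match(dataset$class_index, vars),
              states = dataset$states[vars])
}

# Mixed-radix parent-configuration index, LAST parent fastest. This order is
# the package-wide contract shared by frequency tables, CPT rows and BIF
# output. j ranges over 1..prod(r[parents]).
parent_config_index <- function(x, parents, cardinalities) {
  n <- if (is.matrix(x)) nrow(x) else 1L
  if (length(parents) == 0L) return(rep.int(1L, n))
  w <- rev(cumprod(rev(c(cardinalities[parents][-1L], 1L))))
  sub <- if (is.matrix(x)) x[, parents, drop = FALSE] else
    matrix(x[parents], nrow = 1L)
  as.integer(1L + (sub - 1L) %*% w)
}

# Enumerate all parent configurations in the canonical order: a q x m matrix
# whose j-th row is the state vector of configuration j.
parent_config_grid <- function(parents, cardinalities) {
  if (length(parents) == 0L)
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  r <- cardinalities[parents]
  grid <- expand.grid(rev(lapply(r, seq_len)), KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid[, rev(seq_along(r)), drop = FALSE])
}

#' Conditional frequency table CFT(Xi, Z)
#'
#' Tallies `N_ijk`, the number of rows with `Xi = k` while the parent set `Z`
#' is in its j-th joint configuration, plus the configuration marginals `N_j`.
#' Parent configurations are enumerated in a fixed mixed-radix order with the
#' last parent varying fastest. An empty parent set gives `q = 1`, i.e. the
#' marginal (joint) table.
#'
#' @param dataset an [anb_dataset].
#' @param child child variable index.
#' @param parents integer vector of parent indices (may be empty).
#' @return object of class `anb_cft` with `counts` (q x r matrix),
#'   `marginals` (`N_j`), `child`, `parents`, `q`, `r`.
#' @export
build_cft <- function(dataset, child, parents = integer()) {
  parents <- as.integer(parents)
  child <- as.integer(child)
  p <- length(dataset$vars)
  if (child < 1L || child > p || any(parents < 1L) || any(parents > p))
    stop("invalid variable index")
  if (child %in% parents) stop("child cannot be its own parent")
  r <- dataset$cardinalities[child]
  q <- prod(as.numeric(dataset$cardinalities[parents]))
  if (q > 1e7) stop("parent configuration space too large (q > 1e7)")
  q <- as.integer(q)
  if (nrow(dataset$x)) {
    j <- parent_config_index(dataset$x, parents, dataset$cardinalities)
    k <- dataset$x[, child]
    counts <- matrix(tabulate(j + q * (k - 1L), nbins = q * r), nrow = q)
  } else {
    counts <- matrix(0L, nrow = q, ncol = r)
  }
  structure(
    list(child = child, parents = parents, counts = counts,
         marginals = rowSums(counts), q = q, r = r),
    class = "anb_cft")
}

#' @export
print.anb_cft <- function(x, ...) {
  cat(sprintf("CFT(X%d | {%s}): q = %d configurations, r = %d states, N = %d\n",
              x$child - 1L, paste(x$parents - 1L, collapse = ","),
              x$q, x$r, sum(x$counts)))
  invisible(x)
}
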