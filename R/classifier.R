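#' Discrete Bayesian-network models
#'
#' A `bn_model` couples a DAG with one conditional probability table (CPT) per
#' variable: a `q x r` matrix whose j-th row is the distribution of the
#' variable given the j-th parent configuration (mixed-radix order, last
#' parent fastest). A model doubles as a generative ground truth (for
#' sampling) and as a fitted classifier.
#'
#' @param structure a [bn_structure].
#' @param cpts list of q x r row-stochastic matrices, one per variable.
#' @param states named list of state-label vectors per variable.
#' @param prior optional description of how the parameters were estimated.
#' @return object of class `bn_model`.
#' @export
bn_model <- function(structure, cpts, states, prior = NULL) {
  n <- structure$n_vars
  if (length(cpts) != n || length(states) != n)
    stop("cpts/states length must match the variable count")
  cardinalities <- vapply(states, length, integer(1))
  for (i in seq_len(n)) {
    q <- prod(as.numeric(cardinalities[structure$parents[[i]]]))
    cpt <- cpts[[i]]
    if (nrow(cpt) != q || ncol(cpt) != cardinalities[i])
      stop("CPT shape mismatch for variable ", structure$names[i])
    if (any(cpt < 0) || any(abs(rowSums(cpt) - 1) > 1e-6))
      stop("CPT row of variable ", structure$names[i],
           " is not a probability distribution")
  }
  structure(
    list(structure = structure, cpts = cpts, states = states,
         cardinalities = unname(cardinalities), prior = prior),
    class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf("bn_model: %d variables, %d edges%s\n",
              x$structure$n_vars, sum(lengths(x$structure$parents)),
              if (!is.na(x$structure$class_index))
                paste0(" (class: ",
                       x$structure$names[x$structure$class_index], ")")
              else ""))
  invisible(x)
}

#' EAP parameter estimation
#'
#' Expected a posteriori estimates under a Dirichlet prior:
#' `theta_ijk = (N'_ijk + N_ijk) / (N'_ij + N_j)` with the score-coherent
#' hyperparameters `N'_ijk = ess / (r_i q_Pai)`. The default `ess = 1`
#' reproduces the standard choice `N'_ijk = 1/(r_i q_Pai)`. Parent
#' configurations never observed fall back to the prior-only (uniform)
#' estimate, which is exactly what the formula yields at zero counts.
#'
#' @param dataset an [anb_dataset].
#' @param structure a [bn_structure] over the dataset's variables.
#' @param ess prior strength N' scaling the hyperparameters.
#' @return a [bn_model] with fitted CPTs.
#' @export
fit_eap <- function(dataset, structure, ess = 1) {
  if (ess <= 0) stop("ess must be positive")
  n <- structure$n_vars
  if (n != length(dataset$vars))
    stop("structure and dataset variable counts differ")
  cpts <- vector("list", n)
  for (i in seq_len(n)) {
    cft <- build_cft(dataset, i, structure$parents[[i]])
    a_jk <- ess / (cft$r * cft$q)
    a_j <- ess / cft$q
    cpts[[i]] <- (a_jk + cft$counts) / (a_j + cft$marginals)
  }
  bn_model(structure, cpts, dataset$states,
           prior = list(rule = "eap_bdeu", ess = ess))
}

#' Class posterior given a feature assignment
#'
#' Implements the Markov-blanket classification rule: for each class value c
#' the unnormalized posterior multiplies the class CPT entry (given the
#' configuration of the class variable's parents) by the CPT entries of every
#' child of the class variable (given their parents, with the class slot set
#' to c). Variables outside the Markov blanket of the class cancel in the
#' normalization and never affect the result. Computation is in log space
#' with log-sum-exp normalization.
#'
#' @param model a [bn_model] whose structure designates a class variable.
#' @param x integer vector of state indices, one slot per model variable
#'   (the class slot is ignored); `NA` allowed outside the Markov blanket.
#' @return probability vector over class states (sums to 1).
#' @export
class_posterior <- function(model, x) {
  g <- model$structure
  c0 <- g$class_index
  if (is.na(c0)) stop("model has no designated class variable")
  x <- as.integer(x)
  if (length(x) != g$n_vars)
    stop("x must assign one slot per model variable")
  mb <- markov_blanket(g, c0)
  if (any(is.na(x[mb])))
    stop("missing value for Markov-blanket variable(s): ",
         paste(g$names[mb[is.na(x[mb])]], collapse = ", "))
  r0 <- model$cardinalities[c0]
  ch <- children_of(g, c0)
  logp <- numeric(r0)
  xx <- x
  for (c in seq_len(r0)) {
    xx[c0] <- c
    j0 <- parent_config_index(xx, g$parents[[c0]], model$cardinalities)
    acc <- log(model$cpts[[c0]][j0, c])
    for (i in ch) {
      j <- parent_config_index(xx, g$parents[[i]], model$cardinalities)
      acc <- acc + log(model$cpts[[i]][j, xx[i]])
    }
    logp[c] <- acc
  }
  m <- max(logp)
  p <- exp(logp - m)
  p <- p / sum(p)
  names(p) <- model$states[[c0]]
  p
}

#' Predict class labels
#'
#' Argmax of [class_posterior()] per row; posterior ties break toward the
#' lowest class index.
#'
#' @param object a fitted [bn_model].
#' @param newdata an [anb_dataset], data.frame, or matrix of state indices.
#'   Columns are matched to model variables by name; data.frame values are
#'   matched against the model's state labels.
#' @param type `"class"` for labels (default), `"posterior"` for the full
#'   posterior matrix, `"index"` for 1-based class state indices.
#' @param ... unused.
#' @return character vector of labels, integer vector, or numeric matrix.
#' @export
predict.bn_model <- function(object, newdata,
                             type = c("class", "posterior", "index"), ...) {
  type <- match.arg(type)
  x <- encode_for_model(object, newdata)
  n <- nrow(x)
  r0 <- object$cardinalities[object$structure$class_index]
  post <- matrix(NA_real_, nrow = n, ncol = r0)
  for (d in seq_len(n)) post[d, ] <- class_posterior(object, x[d, ])
  colnames(post) <- object$states[[object$structure$class_index]]
  if (type == "posterior") return(post)
  idx <- apply(post, 1L, which.max)  # which.max: first (lowest) index on ties
  if (type == "index") return(as.integer(idx))
  object$states[[object$structure$class_index]][idx]
}

# Map arbitrary input columns onto the model's variable order/state coding.
# Missing columns (e.g. the class column of a test set, or variables dropped
# by feature selection from a wider table) become NA slots.
encode_for_model <- function(model, newdata) {
  g <- model$structure
  if (inherits(newdata, "anb_dataset")) {
    cols <- match(g$names, newdata$vars)
    x <- matrix(NA_integer_, nrow = nrow(newdata$x), ncol = g$n_vars)
    for (i in seq_len(g$n_vars)) {
      if (is.na(cols[i])) next
      v <- newdata$x[, cols[i]]
      remap <- match(newdata$states[[cols[i]]], model$states[[i]])
      x[, i] <- remap[v]
    }
  } else {
    newdata <- as.data.frame(newdata)
    x <- matrix(NA_integer_, nrow = nrow(newdata), ncol = g$n_vars)
    for (i in seq_len(g$n_vars)) {
      if (!g$names[i] %in% names(newdata)) next
      col <- newdata[[g$names[i]]]
      if (is.numeric(col) && all(col == as.integer(col), na.rm = TRUE) &&
          !is.factor(col))
        x[, i] <- as.integer(col)
      else
        x[, i] <- match(as.character(col), model$states[[i]])
    }
  }
  x
}

#' Naive Bayes structure
#'
#' The class variable is the sole parent of every feature.
#'
#' @param dataset an [anb_dataset].
#' @return a [bn_structure] (a valid ANB structure).
#' @export
naive_bayes_structure <- function(dataset) {
  c0 <- dataset$class_index
  parents <- lapply(seq_along(dataset$vars), function(i)
    if (i == c0) integer(0) else c0)
  bn_structure(parents, names = dataset$vars, class_index = c0)
}
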