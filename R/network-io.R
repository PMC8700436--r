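#' Read and write discrete networks
#'
#' Two on-disk formats are supported, chosen by file extension:
#' \describe{
#'   \item{`.bif`}{a bnlearn-compatible subset of the BIF format (`network`,
#'     `variable`, `probability` blocks; `table` lines for root variables and
#'     per-configuration rows otherwise). A `property class <name> ;` line in
#'     the network block optionally marks the class variable.}
#'   \item{`.json`}{the package's JSON dialect: an object with `name`,
#'     optional `class`, and `nodes`, each node carrying `states`, `parents`
#'     and a `cpt` (list of q rows of r probabilities, parent configurations
#'     in mixed-radix order with the last parent fastest).}
#' }
#' `read_network(write_network(m))` is the identity up to float formatting.
#'
#' @param path file path ending in `.bif` or `.json`.
#' @return a [bn_model].
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_network_json(path)
  else read_network_bif(path)
}

#' @param model a [bn_model].
#' @rdname read_network
#' @export
write_network <- function(model, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    write_network_json(model, path)
  else write_network_bif(model, path)
  invisible(path)
}

write_network_bif <- function(model, path) {
  g <- model$structure
  fmt <- function(p) paste(formatC(p, format = "fg", digits = 15),
                           collapse = ", ")
  out <- c("network unknown {")
  if (!is.na(g$class_index))
    out <- c(out, sprintf("  property class %s ;", g$names[g$class_index]))
  out <- c(out, "}")
  for (i in seq_len(g$n_vars)) {
    out <- c(out,
      sprintf("variable %s {", g$names[i]),
      sprintf("  type discrete [ %d ] { %s };", model$cardinalities[i],
              paste(model$states[[i]], collapse = ", ")),
      "}")
  }
  for (i in seq_len(g$n_vars)) {
    pa <- g$parents[[i]]
    cpt <- model$cpts[[i]]
    if (!length(pa)) {
      out <- c(out,
        sprintf("probability ( %s ) {", g$names[i]),
        sprintf("  table %s;", fmt(cpt[1L, ])),
        "}")
    } else {
      out <- c(out, sprintf("probability ( %s | %s ) {", g$names[i],
                            paste(g$names[pa], collapse = ", ")))
      grid <- parent_config_grid(pa, model$cardinalities)
      for (j in seq_len(nrow(grid))) {
        labs <- vapply(seq_along(pa), function(t)
          model$states[[pa[t]]][grid[j, t]], character(1))
        out <- c(out, sprintf("  ( %s ) %s;",
                              paste(labs, collapse = ", "), fmt(cpt[j, ])))
      }
      out <- c(out, "}")
    }
  }
  writeLines(out, path)
}

read_network_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  class_name <- NA_character_
  m <- regmatches(txt, regexec("property\\s+class\\s+([^\\s;]+)\\s*;", txt,
                               perl = TRUE))[[1]]
  if (length(m) == 2L) class_name <- m[2L]
  # variable blocks
  var_pat <- "variable\\s+([^\\s{]+)\\s*\\{[^}]*?discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}"
  vm <- gregexpr(var_pat, txt, perl = TRUE)
  vars <- character(0); states <- list()
  for (s in regmatches(txt, vm)[[1]]) {
    g <- regmatches(s, regexec(var_pat, s, perl = TRUE))[[1]]
    nm <- g[2L]
    st <- trimws(strsplit(g[4L], ",")[[1]])
    if (length(st) != as.integer(g[3L]))
      stop("state count mismatch for variable ", nm)
    vars <- c(vars, nm)
    states[[nm]] <- st
  }
  if (!length(vars)) stop("no variable blocks found in ", path)
  cardinalities <- vapply(states, length, integer(1))[vars]
  p <- length(vars)
  parents <- rep(list(integer(0)), p)
  cpts <- vector("list", p)
  # probability blocks
  pb_pat <- "probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(pb_pat, txt, perl = TRUE)
  for (s in regmatches(txt, pm)[[1]]) {
    g <- regmatches(s, regexec(pb_pat, s, perl = TRUE))[[1]]
    head <- trimws(strsplit(g[2L], "\\|")[[1]])
    child <- match(trimws(head[1L]), vars)
    if (is.na(child)) stop("unknown variable in probability block: ", head[1L])
    pa <- integer(0)
    if (length(head) > 1L) {
      pa <- match(trimws(strsplit(head[2L], ",")[[1]]), vars)
      if (anyNA(pa)) stop("unknown parent in probability block for ",
                          vars[child])
    }
    parents[[child]] <- pa
    q <- prod(as.numeric(cardinalities[pa]))
    r <- cardinalities[child]
    cpt <- matrix(NA_real_, nrow = q, ncol = r)
    body <- g[3L]
    if (!length(pa)) {
      tm <- regmatches(body, regexec("table([^;]*);", body))[[1]]
      if (length(tm) != 2L) stop("missing table line for ", vars[child])
      vals <- as.numeric(trimws(strsplit(tm[2L], ",")[[1]]))
      if (length(vals) != r) stop("CPT shape mismatch for ", vars[child])
      cpt[1L, ] <- vals
    } else {
      row_pat <- "\\(([^)]*)\\)([^;]*);"
      rm_ <- gregexpr(row_pat, body, perl = TRUE)
      rows <- regmatches(body, rm_)[[1]]
      if (length(rows) != q)
        stop("CPT shape mismatch for ", vars[child], ": expected ", q,
             " configuration rows, found ", length(rows))
      for (rw in rows) {
        gg <- regmatches(rw, regexec(row_pat, rw, perl = TRUE))[[1]]
        labs <- trimws(strsplit(gg[2L], ",")[[1]])
        if (length(labs) != length(pa))
          stop("configuration arity mismatch for ", vars[child])
        conf <- vapply(seq_along(pa), function(t) {
          k <- match(labs[t], states[[vars[pa[t]]]])
          if (is.na(k)) stop("unknown state ", labs[t], " of ", vars[pa[t]])
          k
        }, integer(1))
        j <- parent_config_index(conf, seq_along(pa),
                                 cardinalities[pa])
        vals <- as.numeric(trimws(strsplit(gg[3L], ",")[[1]]))
        if (length(vals) != r) stop("CPT shape mismatch for ", vars[child])
        cpt[j, ] <- vals
      }
    }
    if (anyNA(cpt)) stop("incomplete CPT for ", vars[child])
    cpts[[child]] <- cpt
  }
  if (any(vapply(cpts, is.null, logical(1))))
    stop("missing probability block for some variable")
  class_index <- if (!is.na(class_name)) match(class_name, vars)
                 else NA_integer_
  st <- bn_structure(parents, names = vars, class_index = class_index)
  bn_model(st, cpts, states[vars])
}

write_network_json <- function(model, path) {
  g <- model$structure
  nodes <- lapply(seq_len(g$n_vars), function(i) {
    list(name = g$names[i],
         states = model$states[[i]],
         parents = as.list(g$names[g$parents[[i]]]),
         cpt = lapply(seq_len(nrow(model$cpts[[i]])),
                      function(j) model$cpts[[i]][j, ]))
  })
  obj <- list(name = "unknown", nodes = nodes)
  if (!is.na(g$class_index)) obj$class <- g$names[g$class_index]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- obj$nodes
  vars <- vapply(nodes, function(n) n$name, character(1))
  states <- lapply(nodes, function(n) unlist(n$states))
  names(states) <- vars
  cardinalities <- vapply(states, length, integer(1))
  parents <- lapply(nodes, function(n) {
    pa <- match(unlist(n$parents), vars)
    if (anyNA(pa)) stop("unknown parent of ", n$name)
    pa
  })
  cpts <- lapply(seq_along(nodes), function(i) {
    rows <- lapply(nodes[[i]]$cpt, unlist)
    q <- prod(as.numeric(cardinalities[parents[[i]]]))
    if (length(rows) != q ||
        any(vapply(rows, length, integer(1)) != cardinalities[i]))
      stop("CPT shape mismatch for ", vars[i])
    do.call(rbind, rows)
  })
  class_index <- if (!is.null(obj$class)) match(obj$class, vars)
                 else NA_integer_
  st <- bn_structure(parents, names = vars, class_index = class_index)
  bn_model(st, cpts, states)
}
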