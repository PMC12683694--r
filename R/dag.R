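#' Construct a causal directed acyclic graph
#'
#' A lightweight DAG container for backdoor-criterion covariate selection:
#' nodes, directed edges, an exposure, an outcome, and a set of nodes
#' flagged unobserved (never eligible for adjustment).
#'
#' @param edges two-column matrix or data frame (`from`, `to`), or a
#'   character vector of `"A -> B"` strings.
#' @param exposure,outcome node names; must be distinct and present.
#' @param unobserved character vector of unobserved node names.
#' @param nodes optional additional isolated nodes.
#' @return object of class `causal_dag`.
#' @export
causal_dag <- function(edges, exposure, outcome, unobserved = character(),
                       nodes = character()) {
  if (is.character(edges) && is.null(dim(edges))) {
    edges <- do.call(rbind, lapply(edges, function(s) {
      parts <- strsplit(trimws(s), "\\s*->\\s*")[[1]]
      if (length(parts) != 2L) stop("cannot parse edge: '", s, "'")
      parts
    }))
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  colnames(edges) <- c("from", "to")
  nodes <- unique(c(as.vector(edges), exposure, outcome, unobserved, nodes))
  if (!exposure %in% nodes || !outcome %in% nodes)
    stop("exposure and outcome must be nodes of the graph")
  if (identical(exposure, outcome)) stop("exposure must differ from outcome")
  dag <- structure(list(nodes = nodes, edges = edges, exposure = exposure,
                        outcome = outcome, unobserved = unobserved),
                   class = "causal_dag")
  if (is_cyclic(dag)) stop("graph contains a directed cycle")
  dag
}

#' Read a DAG from a plain-text file
#'
#' One `A -> B` edge per line; lines of the form `unobserved: X` flag nodes
#' as unobserved; `#` starts a comment.
#'
#' @param path file path.
#' @inheritParams causal_dag
#' @return a [causal_dag()].
#' @export
read_dag <- function(path, exposure, outcome) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unobs <- sub("^unobserved:\\s*", "", lines[grepl("^unobserved:", lines)])
  edges <- lines[grepl("->", lines, fixed = TRUE)]
  causal_dag(edges, exposure, outcome, unobserved = unobs)
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("Causal DAG: %d nodes, %d edges (exposure: %s, outcome: %s)\n",
              length(x$nodes), nrow(x$edges), x$exposure, x$outcome))
  if (length(x$unobserved))
    cat("  unobserved:", paste(x$unobserved, collapse = ", "), "\n")
  invisible(x)
}

dag_parents <- function(dag, v) dag$edges[dag$edges[, 2] == v, 1]
dag_children <- function(dag, v) dag$edges[dag$edges[, 1] == v, 2]

dag_descendants <- function(dag, v, include_self = TRUE) {
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(lapply(frontier, dag_children, dag = dag))),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) seen else setdiff(seen, v)
}

is_cyclic <- function(dag) {
  ## Kahn's algorithm
  nodes <- dag$nodes
  edges <- dag$edges
  repeat {
    indeg <- table(factor(edges[, 2], levels = nodes))
    leaves <- nodes[indeg == 0]
    if (!length(leaves)) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!(edges[, 1] %in% leaves), , drop = FALSE]
    if (!length(nodes)) return(FALSE)
  }
  length(nodes) > 0
}

## all simple paths between a and b, ignoring edge direction; each path is
## a list of (node sequence, direction sequence) with direction "->" or "<-"
all_undirected_paths <- function(dag, a, b) {
  adj <- rbind(dag$edges, dag$edges[, 2:1, drop = FALSE])
  paths <- list()
  walk <- function(v, nodes, dirs) {
    if (v == b) {
      paths[[length(paths) + 1L]] <<- list(nodes = nodes, dirs = dirs)
      return(invisible())
    }
    fwd <- dag$edges[dag$edges[, 1] == v, 2]
    bwd <- dag$edges[dag$edges[, 2] == v, 1]
    for (w in fwd) if (!w %in% nodes) walk(w, c(nodes, w), c(dirs, "->"))
    for (w in bwd) if (!w %in% nodes) walk(w, c(nodes, w), c(dirs, "<-"))
  }
  walk(a, a, character(0))
  paths
}

## is a single path d-open given conditioning set Z?
path_open <- function(dag, path, Z) {
  nodes <- path$nodes; dirs <- path$dirs
  n <- length(nodes)
  if (n == 2L) return(TRUE)
  for (m in 2:(n - 1L)) {
    collider <- dirs[m - 1L] == "->" && dirs[m] == "<-"
    if (collider) {
      desc <- dag_descendants(dag, nodes[m])
      if (!any(desc %in% Z)) return(FALSE)
    } else {
      if (nodes[m] %in% Z) return(FALSE)
    }
  }
  TRUE
}

#' Test d-separation
#'
#' Are `a` and `b` d-separated given the conditioning set `Z`?  Evaluated
#' by enumerating undirected simple paths and applying the chain / fork /
#' collider blocking rules (a collider is open when it or a descendant is
#' conditioned on).
#'
#' @param dag a [causal_dag()].
#' @param a,b node names.
#' @param Z character vector of conditioning nodes.
#' @return logical.
#' @export
d_separated <- function(dag, a, b, Z = character()) {
  paths <- all_undirected_paths(dag, a, b)
  !any(vapply(paths, path_open, logical(1), dag = dag, Z = Z))
}

#' Open backdoor paths from exposure to outcome
#'
#' Lists every path from the exposure to the outcome that begins with an
#' edge *into* the exposure and is d-open given the adjustment set.  An
#' empty result means the adjustment set blocks all backdoor paths.
#'
#' @param dag a [causal_dag()].
#' @param adjustment_set character vector of adjusted nodes.
#' @return list of paths; each path is a character vector of node names
#'   with a `dirs` attribute giving the arrow directions.
#' @export
open_backdoor_paths <- function(dag, adjustment_set = character()) {
  paths <- all_undirected_paths(dag, dag$exposure, dag$outcome)
  back <- Filter(function(p) p$dirs[1] == "<-", paths)
  open <- Filter(function(p) path_open(dag, p, adjustment_set), back)
  lapply(open, function(p) structure(p$nodes, dirs = p$dirs))
}

#' Minimal backdoor adjustment sets
#'
#' All minimal sets of observed nodes satisfying the backdoor criterion for
#' the total effect of the exposure on the outcome: no member is a
#' descendant of the exposure, and every backdoor path is blocked.
#'
#' @param dag a [causal_dag()].
#' @return list of character vectors (possibly containing the empty set).
#'   If no observed set is valid, an empty list with attribute
#'   `identifiable = FALSE`.
#' @export
minimal_adjustment_sets <- function(dag) {
  desc_x <- dag_descendants(dag, dag$exposure)
  candidates <- setdiff(dag$nodes,
                        c(desc_x, dag$outcome, dag$unobserved))
  valid <- list()
  for (k in 0:length(candidates)) {
    sets <- if (k == 0) list(character(0)) else
      apply(utils::combn(candidates, k), 2, identity, simplify = FALSE)
    for (S in sets) {
      if (any(vapply(valid, function(v) all(v %in% S), logical(1))))
        next  # superset of an already-minimal set
      if (length(open_backdoor_paths(dag, S)) == 0L)
        valid[[length(valid) + 1L]] <- S
    }
  }
  if (!length(valid)) attr(valid, "identifiable") <- FALSE
  valid
}

#' Conditional independencies implied by a DAG
#'
#' For every pair of non-adjacent observed nodes, finds a smallest observed
#' d-separating set and emits the statement `A _||_ B | Z`.  Pairs with no
#' observed separating set are skipped (they imply no testable constraint
#' on observed data).
#'
#' @param dag a [causal_dag()].
#' @return list of statements, each a list with `a`, `b`, `given`.
#' @seealso [test_independencies()]
#' @export
implied_independencies <- function(dag) {
  obs <- setdiff(dag$nodes, dag$unobserved)
  adj <- paste(dag$edges[, 1], dag$edges[, 2])
  out <- list()
  if (length(obs) < 2L) return(out)
  prs <- utils::combn(obs, 2)
  for (c_i in seq_len(ncol(prs))) {
    a <- prs[1, c_i]; b <- prs[2, c_i]
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    rest <- setdiff(obs, c(a, b))
    found <- NULL
    for (k in 0:length(rest)) {
      sets <- if (k == 0) list(character(0)) else
        apply(utils::combn(rest, k), 2, identity, simplify = FALSE)
      for (S in sets) if (d_separated(dag, a, b, S)) { found <- S; break }
      if (!is.null(found)) break
    }
    if (!is.null(found))
      out[[length(out) + 1L]] <- list(a = a, b = b, given = found)
  }
  out
}

#' Test implied independencies on data by partial correlation
#'
#' Gaussian check of each `A _||_ B | Z` statement: residualize `A` and `B`
#' on `Z` by least squares and test the correlation of the residuals, with
#' degrees of freedom reduced by `|Z|`.
#'
#' @param statements list from [implied_independencies()].
#' @param data data frame with numeric columns named after the DAG nodes.
#' @param alpha significance level used to flag failures.
#' @return data frame with one row per statement: `a`, `b`, `given`,
#'   `partial_cor`, `p_value`, `consistent` (p > alpha).
#' @export
test_independencies <- function(statements, data, alpha = 0.05) {
  rows <- lapply(statements, function(s) {
    need <- c(s$a, s$b, s$given)
    miss <- setdiff(need, names(data))
    if (length(miss)) stop("data is missing column(s): ",
                           paste(miss, collapse = ", "))
    resid_on <- function(v) {
      if (!length(s$given)) return(data[[v]] - mean(data[[v]]))
      stats::resid(stats::lm(stats::reformulate(s$given, v), data = data))
    }
    ra <- resid_on(s$a); rb <- resid_on(s$b)
    r <- stats::cor(ra, rb)
    n <- length(ra); df <- n - length(s$given) - 2L
    tval <- r * sqrt(df / (1 - r^2))
    pval <- 2 * stats::pt(-abs(tval), df)
    data.frame(a = s$a, b = s$b,
               given = paste(s$given, collapse = ","),
               partial_cor = r, p_value = pval,
               consistent = pval > alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
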