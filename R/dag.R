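## Directed acyclic graph models over trait names, the candidate model sets
## for the demography -> ASR -> breeding-system hypotheses, and Shipley
## d-separation basis sets.

#' Construct a DAG model
#'
#' @param edges Two-column matrix or data frame of directed edges
#'   (cause, effect); may have zero rows.
#' @param nodes Character vector of node names (defaults to the union of
#'   edge endpoints).
#' @param label Model identifier (e.g. `"1a"`).
#' @param coefficients Optional numeric vector of standardized path weights,
#'   one per edge.
#' @return List of class `dag_model`: `nodes`, `edges`, `label`,
#'   `coefficients`.
#' @export
dag_model <- function(edges, nodes = NULL, label = "", coefficients = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(0), 0, 2)
  }
  if (ncol(edges) != 2) stop("edges must have two columns (cause, effect)")
  colnames(edges) <- c("from", "to")
  if (is.null(nodes)) nodes <- unique(c(edges))
  if (!all(c(edges) %in% nodes)) stop("edge endpoint not in node set")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  if (!is.null(coefficients) && length(coefficients) != nrow(edges))
    stop("one coefficient per edge required")
  m <- structure(list(nodes = nodes, edges = edges, label = label,
                      coefficients = coefficients),
                 class = "dag_model")
  if (is.null(topological_order(m))) stop("graph is cyclic; a DAG is required")
  m
}

#' Topological order of a DAG (NULL if cyclic)
#' @param dag A `dag_model`.
#' @return Character vector of nodes in topological order, ties broken by
#'   sorted name, or `NULL` for cyclic graphs.
#' @export
topological_order <- function(dag) {
  nodes <- sort(dag$nodes)
  edges <- dag$edges
  order_out <- character(0)
  indeg <- setNames(vapply(nodes, function(n) sum(edges[, 2] == n), 0L), nodes)
  active <- nodes
  while (length(active)) {
    free <- active[indeg[active] == 0]
    if (!length(free)) return(NULL)
    v <- free[1]
    order_out <- c(order_out, v)
    active <- setdiff(active, v)
    kids <- edges[edges[, 1] == v, 2]
    indeg[kids] <- indeg[kids] - 1L
  }
  order_out
}

#' Parents of a node
#' @param dag A `dag_model`.
#' @param node Node name.
#' @return Character vector of parent nodes.
#' @export
dag_parents <- function(dag, node) {
  unname(dag$edges[dag$edges[, 2] == node, 1])
}

## Internal: adjacency (either direction).
dag_adjacent <- function(dag, a, b) {
  e <- dag$edges
  any((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
}

#' The candidate path-model sets for the ASR hypotheses
#'
#' Six directed acyclic graphs over demography bias, ASR and the breeding
#' system components. The H1 family has demography bias driving ASR, which
#' drives the breeding-system traits: variant 1a with no edges among the
#' breeding traits, 1b with ASR -> pre-copulatory bias -> care, and 1c with
#' ASR -> care -> pre-copulatory bias. The H2 family mirrors the mediation:
#' the breeding traits drive demography bias, which drives ASR (so H2 models
#' contain no edge out of ASR).
#'
#' @param include_postcop Include the post-copulatory bias node (imputed
#'   data set) or not (raw-data set).
#' @return Named list of six `dag_model`s labelled `1a`,`1b`,`1c`,`2a`,
#'   `2b`,`2c`.
#' @export
candidate_models <- function(include_postcop = TRUE) {
  pc <- include_postcop
  e <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  h1_base <- e("demography_bias", "asr")
  m <- list()
  m[["1a"]] <- rbind(h1_base,
                     e("asr", "precop_bias", "asr", "care_bias"),
                     if (pc) e("asr", "postcop_bias"))
  m[["1b"]] <- rbind(h1_base,
                     e("asr", "precop_bias", "precop_bias", "care_bias"),
                     if (pc) e("asr", "postcop_bias"))
  m[["1c"]] <- rbind(h1_base,
                     e("asr", "care_bias", "care_bias", "precop_bias"),
                     if (pc) e("asr", "postcop_bias"))
  h2_base <- e("demography_bias", "asr")
  m[["2a"]] <- rbind(e("precop_bias", "demography_bias",
                       "care_bias", "demography_bias"),
                     if (pc) e("postcop_bias", "demography_bias"),
                     h2_base)
  m[["2b"]] <- rbind(e("precop_bias", "care_bias",
                       "care_bias", "demography_bias"),
                     if (pc) e("postcop_bias", "demography_bias"),
                     h2_base)
  m[["2c"]] <- rbind(e("care_bias", "precop_bias",
                       "precop_bias", "demography_bias"),
                     if (pc) e("postcop_bias", "demography_bias"),
                     h2_base)
  nodes <- c("demography_bias", "asr", "precop_bias", "care_bias",
             if (pc) "postcop_bias")
  out <- lapply(names(m), function(lb) dag_model(m[[lb]], nodes = nodes, label = lb))
  names(out) <- names(m)
  out
}

#' Shipley d-separation basis set of a DAG
#'
#' One conditional-independence claim per non-adjacent node pair: the later
#' node in topological order is (canonically) regressed on the earlier one,
#' conditioning on the union of the parents of both (excluding the pair
#' itself). Claims are ordered deterministically by topological rank of the
#' response, then by name.
#'
#' @param dag A `dag_model`.
#' @return List of claims, each a list with `x` (predictor of interest),
#'   `y` (response), `conditioning` (character vector).
#' @export
basis_set <- function(dag) {
  topo <- topological_order(dag)
  if (is.null(topo)) stop("graph is cyclic")
  rank <- setNames(seq_along(topo), topo)
  claims <- list()
  nn <- sort(dag$nodes)
  for (a in nn) for (b in nn) {
    if (a >= b) next
    if (dag_adjacent(dag, a, b)) next
    lo <- if (rank[a] <= rank[b]) a else b
    hi <- if (rank[a] <= rank[b]) b else a
    cond <- setdiff(union(dag_parents(dag, a), dag_parents(dag, b)), c(a, b))
    claims[[length(claims) + 1]] <- list(x = lo, y = hi,
                                         conditioning = sort(cond))
  }
  if (length(claims)) {
    ord <- order(vapply(claims, function(cl) rank[cl$y], 1),
                 vapply(claims, function(cl) cl$y, ""),
                 vapply(claims, function(cl) cl$x, ""))
    claims <- claims[ord]
  }
  claims
}

#' Read a DAG from an edge-list file
#'
#' Format: one `cause<TAB>effect` pair per line, `#` comments allowed.
#'
#' @param path File path.
#' @param label Model label.
#' @return A `dag_model`.
#' @export
read_dag <- function(path, label = basename(path)) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("no edges in ", path)
  parts <- strsplit(ln, "[\t ]+")
  if (any(lengths(parts) != 2)) stop("each line must be 'cause<TAB>effect'")
  dag_model(do.call(rbind, parts), label = label)
}

#' Write a DAG to an edge-list file
#' @param dag A `dag_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  writeLines(paste(dag$edges[, 1], dag$edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' @export
print.dag_model <- function(x, ...) {
  cat(sprintf("DAG '%s': %d nodes, %d edges\n", x$label,
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    co <- if (is.null(x$coefficients)) rep("", nrow(x$edges))
          else sprintf(" (%.2f)", x$coefficients)
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], co, collapse = "\n"), "\n")
  }
  invisible(x)
}
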