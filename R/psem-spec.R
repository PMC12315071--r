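## Causal-graph specification for piecewise SEM.

#' Specify a piecewise SEM causal graph
#'
#' Directed edges are given as `"cause -> effect"` strings (or a
#' two-column `from`/`to` data.frame), correlated errors as
#' `"a ~~ b"` strings.  The graph must be acyclic; duplicate edges and
#' self-loops are rejected, and a deterministic topological order is
#' computed.
#'
#' @param edges Character vector of `"cause -> effect"` strings, or a
#'   `data.frame` with columns `from`, `to`.
#' @param correlated Character vector of `"a ~~ b"` correlated-error
#'   declarations (undirected; removed from the d-separation basis set).
#' @param exogenous Character vector of exogenous node names; claims
#'   between two exogenous nodes are excluded from the basis set.
#' @param group Optional name of the grouping column for multigroup
#'   fits.
#' @return An object of class `psem_spec`.
#' @examples
#' sp <- psem_spec(c("a -> b", "b -> c"))
#' basis_set(sp)
#' @export
psem_spec <- function(edges, correlated = character(),
                      exogenous = character(), group = NULL) {
  ed <- parse_edges(edges, " *-> *")
  if (any(ed$from == ed$to))
    stop_("self-loop on node '%s'", ed$from[ed$from == ed$to][1])
  key <- paste(ed$from, ed$to)
  if (anyDuplicated(key))
    stop_("duplicate edge: %s", sub(" ", " -> ", key[duplicated(key)][1]))
  corr <- if (length(correlated)) parse_edges(correlated, " *~~ *") else
    data.frame(from = character(), to = character())
  nodes <- sort(unique(c(ed$from, ed$to, corr$from, corr$to, exogenous)))
  both <- paste(ed$from, ed$to) %in%
    c(paste(corr$from, corr$to), paste(corr$to, corr$from))
  if (any(both))
    stop_("'%s -> %s' declared both as edge and correlated error",
          ed$from[both][1], ed$to[both][1])
  order <- topo_sort(nodes, ed)
  structure(list(nodes = nodes, edges = ed, correlated = corr,
                 exogenous = intersect(exogenous, nodes),
                 group = group, order = order),
            class = "psem_spec")
}

parse_edges <- function(edges, sep) {
  if (is.data.frame(edges)) {
    assert_cols(edges, c("from", "to"), "edge table")
    return(data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(edges), sep)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop_("cannot parse edge '%s'", edges[bad][1])
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

## Kahn's algorithm, lexicographic tie-break; names the cycle on failure.
topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges$to, levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    avail <- sort(remaining[indeg[remaining] == 0L])
    if (!length(avail)) {
      cyc <- remaining
      stop_("cycle detected among nodes: %s", paste(cyc, collapse = ", "))
    }
    n <- avail[1]
    out <- c(out, n)
    remaining <- setdiff(remaining, n)
    kids <- edges$to[edges$from == n]
    indeg[kids] <- indeg[kids] - 1L
  }
  out
}

#' Validate a pSEM specification against a data table
#'
#' @param spec A `psem_spec`.
#' @param data Optional data.frame; every node (and the grouping
#'   variable, if any) must be a column.
#' @return The spec, invisibly, after checks.
#' @export
validate_spec <- function(spec, data = NULL) {
  if (!inherits(spec, "psem_spec")) stop_("spec must be a psem_spec")
  if (!is.null(data)) {
    missing <- setdiff(c(spec$nodes, spec$group), names(data))
    if (length(missing))
      stop_("data lacks column(s) for node(s): %s",
            paste(missing, collapse = ", "))
  }
  invisible(spec)
}

parents_of <- function(spec, node) sort(spec$edges$from[spec$edges$to == node])

adjacent <- function(spec, a, b) {
  any((spec$edges$from == a & spec$edges$to == b) |
        (spec$edges$from == b & spec$edges$to == a))
}

corr_pair <- function(spec, a, b) {
  nrow(spec$correlated) > 0 &&
    any((spec$correlated$from == a & spec$correlated$to == b) |
          (spec$correlated$from == b & spec$correlated$to == a))
}

#' Shipley basis set of d-separation claims
#'
#' One claim per unordered pair of non-adjacent nodes not declared as a
#' correlated-error pair and not both exogenous.  Each claim takes the
#' topologically later node as response, the earlier as focal
#' predictor, conditioning on the union of both nodes' parents.
#'
#' @param spec A `psem_spec`.
#' @return A list of claims, each
#'   `list(predictor, response, conditioning)`.
#' @export
basis_set <- function(spec) {
  validate_spec(spec)
  ord <- spec$order
  claims <- list()
  n <- length(ord)
  if (n < 2L) return(claims)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      u <- ord[i]; v <- ord[j]          # u earlier, v later
      if (adjacent(spec, u, v)) next
      if (corr_pair(spec, u, v)) next
      if (u %in% spec$exogenous && v %in% spec$exogenous) next
      cond <- setdiff(union(parents_of(spec, u), parents_of(spec, v)),
                      c(u, v))
      claims[[length(claims) + 1L]] <-
        list(predictor = u, response = v, conditioning = sort(cond))
    }
  }
  claims
}

#' @export
print.psem_spec <- function(x, ...) {
  cat(sprintf("Piecewise SEM spec: %d nodes, %d directed edges, %d correlated pair(s)\n",
              length(x$nodes), nrow(x$edges), nrow(x$correlated)))
  cat("  order:", paste(x$order, collapse = " < "), "\n")
  if (!is.null(x$group)) cat("  multigroup by:", x$group, "\n")
  invisible(x)
}

#' The default heterogeneity-stability causal model
#'
#' An a priori DAG for the tile experiment: heterogeneity and emersion
#' act on community components (species richness, the dominant
#' non-native barnacle, consumers, native barnacles, ephemeral algae),
#' which feed the stability mechanisms (population stability,
#' asynchrony, compositional stability) that determine temporal
#' stability; heterogeneity also acts directly on population stability
#' (refugia).  Population stability and asynchrony share a
#' correlated error because both derive from the same per-taxon
#' variability decomposition.
#'
#' @return A `psem_spec` with grouping variable `"zone"`.
#' @export
default_sem_spec <- function() {
  psem_spec(
    edges = c(
      "het -> richness", "het -> dominant", "het -> consumers",
      "het -> pop_stability", "het -> temp_stability",
      "emersion -> richness", "emersion -> dominant",
      "emersion -> consumers", "emersion -> native",
      "emersion -> ephemerals", "emersion -> temp_stability",
      "emersion -> pop_stability", "emersion -> asynchrony",
      "emersion -> comp_stability",
      "consumers -> ephemerals", "consumers -> comp_stability",
      "dominant -> asynchrony", "dominant -> comp_stability",
      "dominant -> pop_stability",
      "richness -> asynchrony", "richness -> pop_stability",
      "consumers -> pop_stability",
      "ephemerals -> pop_stability", "ephemerals -> comp_stability",
      "native -> temp_stability",
      "pop_stability -> comp_stability",
      "asynchrony -> temp_stability",
      "comp_stability -> temp_stability"),
    correlated = "pop_stability ~~ asynchrony",
    exogenous = c("het", "emersion"),
    group = "zone")
}
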