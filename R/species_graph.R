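#' Overlap between two organisms' overrepresented-term lists
#'
#' Counts the common terms and expresses the overlap relative to the
#' maximum possible overlap, `min(|A|, |B|)`.
#'
#' @param list_a,list_b Character vectors of term IDs (any annotation
#'   category; treated as opaque IDs).
#' @return List: count, relative. Both zero when either list is empty.
#' @export
term_overlap <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  count <- length(intersect(a, b))
  denom <- min(length(a), length(b))
  list(count = count,
       relative = if (denom > 0) count / denom else 0)
}

#' Build the species similarity graph from shared overrepresented terms
#'
#' Nodes are organisms; an edge is kept when the pair shares at least
#' `min_count` terms and the overlap covers at least `min_relative` of
#' the maximum possible overlap. Edge weight is the shared-term count.
#'
#' @param term_lists Named list organism ID -> character vector of
#'   overrepresented term IDs (>= 2 organisms).
#' @param min_count Minimum shared-term count per edge.
#' @param min_relative Minimum relative overlap per edge.
#' @return Object of class `species_graph`: `nodes` (all organisms) and
#'   `edges` (data frame source < target, weight, relative).
#' @export
build_graph <- function(term_lists, min_count = 10, min_relative = 0.30) {
  stopifnot(length(term_lists) >= 2L, !is.null(names(term_lists)))
  orgs <- sort(names(term_lists))
  edges <- list()
  for (i in seq_len(length(orgs) - 1L)) {
    for (j in seq.int(i + 1L, length(orgs))) {
      ov <- term_overlap(term_lists[[orgs[i]]], term_lists[[orgs[j]]])
      if (ov$count >= min_count && ov$relative >= min_relative) {
        edges[[length(edges) + 1L]] <-
          data.frame(source = orgs[i], target = orgs[j],
                     weight = ov$count, relative = ov$relative,
                     stringsAsFactors = FALSE)
      }
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               weight = numeric(0), relative = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(nodes = orgs, edges = ed), class = "species_graph")
}

#' @export
print.species_graph <- function(x, ...) {
  cat("species graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Summarise a species graph
#'
#' @param graph A `species_graph`.
#' @return List: n_nodes, n_edges, degree (named vector), n_components,
#'   component_sizes (descending).
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "species_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  list(n_nodes = length(graph$nodes),
       n_edges = nrow(graph$edges),
       degree = deg[order(names(deg))],
       n_components = as.integer(comp$no),
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}
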