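#' Construct an ontology DAG
#'
#' Holds a set of terms, their `is_a`/`part_of` edges (child -> parent),
#' per-term namespaces and human-readable names, plus an alternate-ID map.
#' The constructor validates that every edge endpoint is a known term and
#' that the graph is acyclic; a cycle aborts with one offending cycle
#' spelled out.
#'
#' @param terms Character vector of term IDs.
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (values `is_a` or `part_of`).
#' @param namespaces Named character vector term -> namespace
#'   (`process`, `function` or `component`); missing terms default to
#'   `process`.
#' @param term_names Named character vector term -> display name.
#' @param alt Named character vector alt_id -> canonical ID.
#' @return An object of class `onto_dag`.
#' @export
onto_dag <- function(terms, edges = NULL, namespaces = NULL,
                     term_names = NULL, alt = character(0)) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term IDs in ontology")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) stop("unsupported relation(s): ",
                            paste(bad_rel, collapse = ", "))
  missing_ep <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(missing_ep)) {
    stop("edge endpoint(s) not in term set: ",
         paste(head(missing_ep, 5), collapse = ", "))
  }
  ns <- rep("process", length(terms))
  names(ns) <- terms
  if (!is.null(namespaces)) ns[names(namespaces)] <- unname(namespaces)
  nm <- terms
  names(nm) <- terms
  if (!is.null(term_names)) nm[names(term_names)] <- unname(term_names)

  dag <- structure(
    list(terms = terms, edges = edges, namespaces = ns, names = nm,
         alt = alt,
         parents_by_child = split(seq_len(nrow(edges)), edges$child)),
    class = "onto_dag"
  )
  dag_topo_order(dag)  # errors if cyclic
  dag
}

#' @export
print.onto_dag <- function(x, ...) {
  cat("ontology DAG:", length(x$terms), "terms,", nrow(x$edges), "edges (",
      sum(x$edges$relation == "is_a"), "is_a /",
      sum(x$edges$relation == "part_of"), "part_of ),",
      length(dag_roots(x)), "root(s)\n")
  invisible(x)
}

#' Roots of an ontology DAG (terms with no parents)
#' @param dag An `onto_dag`.
#' @return Character vector of root term IDs.
#' @export
dag_roots <- function(dag) {
  setdiff(dag$terms, unique(dag$edges$child))
}

#' Topological order of a DAG (children before parents)
#'
#' Errors with one explicit cycle if the graph is cyclic.
#' @param dag An `onto_dag`.
#' @return Character vector of term IDs in topological order.
#' @export
dag_topo_order <- function(dag) {
  n <- length(dag$terms)
  idx <- seq_len(n)
  names(idx) <- dag$terms
  # Kahn's algorithm on the child -> parent digraph: sources are leaves,
  # so the order emits every child before any of its parents.
  in_deg <- integer(n)
  parents_of <- vector("list", n)
  if (nrow(dag$edges)) {
    ci <- idx[dag$edges$child]
    pi <- idx[dag$edges$parent]
    for (k in seq_along(ci)) {
      in_deg[[pi[k]]] <- in_deg[[pi[k]]] + 1L
      parents_of[[ci[k]]] <- c(parents_of[[ci[k]]], pi[k])
    }
  }
  queue <- which(in_deg == 0L)
  order_out <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    order_out <- c(order_out, v)
    for (p in parents_of[[v]]) {
      in_deg[[p]] <- in_deg[[p]] - 1L
      if (in_deg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order_out) < n) {
    cyc <- find_one_cycle(dag)
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  dag$terms[order_out]
}

#' @noRd
find_one_cycle <- function(dag) {
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(t) {
    if (!is.null(found)) return()
    st <- get0(t, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      i <- match(t, path)
      found <<- c(path[i:length(path)], t)
      return()
    }
    if (st == 2L) return()
    assign(t, 1L, envir = state)
    path <<- c(path, t)
    rows <- dag$parents_by_child[[t]]
    for (p in dag$edges$parent[rows]) visit(p)
    path <<- path[-length(path)]
    assign(t, 2L, envir = state)
  }
  for (t in dag$terms) visit(t)
  found
}

#' Resolve a term ID through the alternate-ID map
#' @param dag An `onto_dag`.
#' @param term Term ID (possibly an alt_id).
#' @return Canonical term ID, or `NA` if unknown.
#' @export
dag_resolve <- function(dag, term) {
  term <- ifelse(term %in% names(dag$alt), unname(dag$alt[term]), term)
  ifelse(term %in% dag$terms, term, NA_character_)
}

#' Ancestors of a term via is_a and part_of edges
#'
#' @param dag An `onto_dag`.
#' @param term A term ID.
#' @param include_self Include the query term itself?
#' @param relations Which relations to traverse.
#' @return Character vector of ancestor term IDs.
#' @export
dag_ancestors <- function(dag, term, include_self = FALSE,
                          relations = c("is_a", "part_of")) {
  t0 <- dag_resolve(dag, term)
  if (is.na(t0)) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- t0
  while (length(frontier)) {
    rows <- unlist(dag$parents_by_child[frontier], use.names = FALSE)
    if (is.null(rows) || !length(rows)) break
    rows <- rows[dag$edges$relation[rows] %in% relations]
    nxt <- setdiff(unique(dag$edges$parent[rows]), c(seen, t0))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  anc <- sort(seen)
  if (include_self) sort(unique(c(anc, t0))) else anc
}

#' Parse an OBO 1.2 ontology file
#'
#' Keeps `is_a` and `relationship: part_of` edges only; obsolete terms are
#' dropped (and edges pointing at them); `alt_id`s are recorded so lookups
#' by an alternate ID resolve to the canonical term.
#'
#' @param path Path to an OBO file.
#' @return An `onto_dag`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  names(ends) <- as.character(stanza_starts)

  terms <- character(0); ns <- character(0); nm <- character(0)
  alt <- character(0); obsolete <- character(0)
  edges <- list()
  for (s in term_starts) {
    block <- lines[seq.int(s + 1L, ends[[as.character(s)]])]
    block <- block[nzchar(block)]
    kv <- regmatches(block, regexec("^([a-z_]+):\\s*(.*)$", block))
    keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else "", "")
    vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else "", "")
    id <- trimws(vals[keys == "id"][1])
    if (is.na(id) || !nzchar(id)) next
    if (any(keys == "is_obsolete" & grepl("true", vals))) {
      obsolete <- c(obsolete, id)
      next
    }
    terms <- c(terms, id)
    if (any(keys == "name")) nm[id] <- trimws(vals[keys == "name"][1])
    if (any(keys == "namespace")) {
      raw <- trimws(vals[keys == "namespace"][1])
      ns[id] <- switch(raw,
                       biological_process = "process",
                       molecular_function = "function",
                       cellular_component = "component",
                       raw)
    }
    for (a in vals[keys == "alt_id"]) alt[trimws(a)] <- id
    for (v in vals[keys == "is_a"]) {
      parent <- trimws(sub("!.*$", "", v))
      edges[[length(edges) + 1L]] <- c(id, parent, "is_a")
    }
    for (v in vals[keys == "relationship"]) {
      parts <- strsplit(trimws(sub("!.*$", "", v)), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        edges[[length(edges) + 1L]] <- c(id, parts[2], "part_of")
      }
    }
  }
  ed <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], relation = m[, 3],
               stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(ed)) {
    drop <- ed$parent %in% obsolete | ed$child %in% obsolete
    if (any(drop)) {
      warning(sum(drop), " edge(s) referencing obsolete terms dropped")
      ed <- ed[!drop, , drop = FALSE]
    }
  }
  onto_dag(terms, ed, namespaces = ns, term_names = nm, alt = alt)
}

#' Ancestor-close (propagate) direct annotations over the ontology
#'
#' Implements the true-path rule: a protein annotated to a term is
#' implicitly annotated to all of that term's ancestors via `is_a` and
#' `part_of` (configurable). Terms unknown to the DAG (after alt-ID
#' resolution) are dropped with a warning; annotations to obsolete terms
#' are unknown by construction and thus dropped too.
#'
#' @param direct Named list: protein ID -> character vector of term IDs.
#' @param dag An `onto_dag`.
#' @param relations Relations to traverse (default both).
#' @return Named list with elements `direct` (resolved, known terms only)
#'   and `propagated` (ancestor-closed sets), each protein ID -> terms.
#' @export
propagate <- function(direct, dag, relations = c("is_a", "part_of")) {
  stopifnot(is.list(direct))
  # cache ancestor sets per term
  cache <- new.env(parent = emptyenv())
  anc_of <- function(t) {
    got <- get0(t, envir = cache, ifnotfound = NULL)
    if (!is.null(got)) return(got)
    a <- dag_ancestors(dag, t, include_self = TRUE, relations = relations)
    assign(t, a, envir = cache)
    a
  }
  dropped <- character(0)
  res_direct <- vector("list", length(direct))
  res_prop <- vector("list", length(direct))
  names(res_direct) <- names(direct)
  names(res_prop) <- names(direct)
  for (p in names(direct)) {
    ts <- as.character(direct[[p]])
    resolved <- vapply(ts, function(t) dag_resolve(dag, t), character(1))
    unknown <- ts[is.na(resolved)]
    dropped <- c(dropped, unknown)
    keep <- resolved[!is.na(resolved)]
    res_direct[[p]] <- sort(unique(unname(keep)))
    res_prop[[p]] <- if (length(keep)) {
      sort(unique(unlist(lapply(unique(unname(keep)), anc_of),
                         use.names = FALSE)))
    } else character(0)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " annotation(s) to unknown term(s): ",
            paste(unique(dropped), collapse = ", "))
  }
  list(direct = res_direct, propagated = res_prop)
}
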