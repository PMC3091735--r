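#' Binarize filtered enrichment results into a species x term matrix
#'
#' Cell (organism, term) is 1 when the term was overrepresented in that
#' organism after the cross-organism filter. Organisms carrying fewer
#' than two terms cannot join any non-trivial bicluster and are flagged
#' as unclusterable and excluded from the matrix. Row and column order is
#' lexicographic for deterministic output.
#'
#' @param enrichment_results Data frame with columns `organism`, `term`
#'   (e.g. from [cross_organism_filter()]).
#' @return List: `matrix` (binary incidence), `unclusterable` (organism
#'   IDs excluded for having < 2 terms).
#' @export
binarize <- function(enrichment_results) {
  stopifnot(is.data.frame(enrichment_results))
  if (!nrow(enrichment_results)) stop("no enrichment results to binarize")
  pairs <- unique(enrichment_results[, c("organism", "term")])
  n_terms <- table(pairs$organism)
  drop <- names(n_terms)[n_terms < 2]
  keep <- pairs[!(pairs$organism %in% drop), , drop = FALSE]
  orgs <- sort(unique(keep$organism))
  terms <- sort(unique(keep$term))
  m <- matrix(0L, nrow = length(orgs), ncol = length(terms),
              dimnames = list(orgs, terms))
  if (nrow(keep)) m[cbind(keep$organism, keep$term)] <- 1L
  list(matrix = m, unclusterable = sort(drop))
}

#' Enumerate inclusion-maximal all-ones biclusters (BiMax)
#'
#' Finds exactly the inclusion-maximal all-ones submatrices of a binary
#' matrix with at least `min_rows` rows and `min_cols` columns. Maximal
#' all-ones submatrices coincide with the formal concepts of the binary
#' relation, enumerated here with a Close-by-One search with canonicity
#' pruning; branches whose row support falls below `min_rows` are cut.
#' Because the number of maximal biclusters can grow exponentially, the
#' enumeration aborts once `max_biclusters` concepts have been collected.
#'
#' @param mat Binary matrix with row and column names.
#' @param min_rows,min_cols Minimum bicluster dimensions (defaults 2 and
#'   2, the smallest non-trivial module).
#' @param max_biclusters Enumeration budget; exceeding it is an error
#'   advising decomposition of the input.
#' @return List of biclusters, each a list with sorted character vectors
#'   `rows` and `cols`; ordered by (|rows| desc, |cols| desc, rows, cols).
#' @export
bimax <- function(mat, min_rows = 2, min_cols = 2, max_biclusters = 1e5) {
  stopifnot(is.matrix(mat), all(mat %in% c(0, 1)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("R%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("C%d", seq_len(ncol(mat)))
  nr <- nrow(mat)
  nc <- ncol(mat)
  storage.mode(mat) <- "integer"
  rows_of_col <- lapply(seq_len(nc), function(j) which(mat[, j] == 1L))

  found <- new.env(parent = emptyenv())
  found$list <- vector("list", 256L)
  found$n <- 0L

  record <- function(rows, cols) {
    if (length(rows) >= min_rows && length(cols) >= min_cols) {
      n <- found$n + 1L
      if (n > max_biclusters) {
        stop("bicluster enumeration budget (", max_biclusters,
             ") exceeded; decompose the matrix or raise max_biclusters")
      }
      if (n > length(found$list)) {
        length(found$list) <- 2L * length(found$list)
      }
      found$list[[n]] <- list(rows = rows, cols = cols)
      found$n <- n
    }
  }

  closure_cols <- function(rows) {
    if (!length(rows)) return(seq_len(nc))
    which(.colSums(mat[rows, , drop = FALSE], length(rows), nc) ==
            length(rows))
  }

  # Close-by-One over column sets; B is closed, A = rows supporting B.
  cbo <- function(A, B, y) {
    for (j in seq_len(nc)) {
      if (j <= y || j %in% B) next
      A2 <- intersect(A, rows_of_col[[j]])
      if (length(A2) < max(min_rows, 1L)) next
      D <- closure_cols(A2)
      # canonicity: no column before j may enter the closure unseen
      if (any(D < j & !(D %in% B))) next
      record(A2, D)
      cbo(A2, D, j)
    }
  }

  A0 <- seq_len(nr)
  B0 <- closure_cols(A0)
  record(A0, B0)
  cbo(A0, B0, 0L)

  out <- found$list[seq_len(found$n)]
  out <- lapply(out, function(b) list(rows = sort(rownames(mat)[b$rows]),
                                      cols = sort(colnames(mat)[b$cols])))
  ord <- order(-vapply(out, function(b) length(b$rows), 0L),
               -vapply(out, function(b) length(b$cols), 0L),
               vapply(out, function(b) paste(b$rows, collapse = ","), ""),
               vapply(out, function(b) paste(b$cols, collapse = ","), ""))
  out[ord]
}

#' Drop biclusters spanning only strains of a single species
#'
#' Clusters whose organisms all map to one species label reflect strain
#' redundancy rather than shared biology and are removed (the per-species
#' removal counts are reported). Organisms missing from the strain map
#' are treated as their own species with a warning.
#'
#' @param biclusters List of biclusters (from [bimax()]).
#' @param strain_map Named character vector organism ID -> species label.
#' @param species Species labels the rule applies to; `NULL` (default)
#'   applies it to every species.
#' @return List: `biclusters` (kept), `removed_by_species` (named counts).
#' @export
drop_single_species_clusters <- function(biclusters, strain_map,
                                         species = NULL) {
  unmapped <- unique(unlist(lapply(biclusters, `[[`, "rows"),
                            use.names = FALSE))
  unmapped <- setdiff(unmapped, names(strain_map))
  if (length(unmapped)) {
    warning("organism(s) missing from strain map treated as own species: ",
            paste(unmapped, collapse = ", "))
    add <- stats::setNames(unmapped, unmapped)
    strain_map <- c(strain_map, add)
  }
  removed <- integer(0)
  keep <- vapply(biclusters, function(b) {
    labs <- unique(unname(strain_map[b$rows]))
    single <- length(labs) == 1L &&
      (is.null(species) || labs %in% species)
    if (single) removed[labs] <<- (if (labs %in% names(removed))
      removed[[labs]] else 0L) + 1L
    !single
  }, logical(1))
  list(biclusters = biclusters[keep], removed_by_species = removed)
}

#' Count organism-term co-occurrences over all biclusters
#'
#' For each (organism, term) pair, counts the biclusters containing both
#' the organism row and the term column. Organisms belonging to
#' `exclude_species` (per the strain map) are removed first, so heavily
#' sequenced species do not inflate the counts.
#'
#' @param biclusters List of biclusters.
#' @param strain_map Named character vector organism -> species label
#'   (only needed when excluding species).
#' @param exclude_species Species labels to drop.
#' @return Data frame: organism, term, count; sorted by organism,
#'   descending count, term.
#' @export
cooccurrence_counts <- function(biclusters, strain_map = NULL,
                                exclude_species = character(0)) {
  rows <- list()
  for (b in biclusters) {
    orgs <- b$rows
    if (length(exclude_species)) {
      labs <- strain_map[orgs]
      orgs <- orgs[is.na(labs) | !(labs %in% exclude_species)]
    }
    if (!length(orgs)) next
    rows[[length(rows) + 1L]] <- expand.grid(organism = orgs, term = b$cols,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(organism = character(0), term = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  all_pairs <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(all_pairs))),
                          by = all_pairs[, c("organism", "term")], FUN = sum)
  agg <- agg[order(agg$organism, -agg$count, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
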