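#' COG category distribution of a protein set
#'
#' Each protein contributes one count per assigned category (a
#' multi-domain protein classified in two categories is registered in
#' both); a protein with no assignment contributes one count to `"-"`.
#' Fractions are over assignments, not proteins.
#'
#' @param protein_ids Character vector of protein IDs.
#' @param cog_map Named list protein ID -> character vector of categories.
#' @param ribosomal_filter Optional character vector of protein IDs to
#'   exclude (e.g. ribosomal proteins); `NULL` keeps everything.
#' @return An object of class `cog_distribution` with `counts` and
#'   `fractions` (named over A-Z plus `"-"`), and `n_assignments`.
#' @export
cog_distribution <- function(protein_ids, cog_map, ribosomal_filter = NULL) {
  cats <- c(LETTERS, "-")
  counts <- stats::setNames(integer(length(cats)), cats)
  if (!is.null(ribosomal_filter)) {
    protein_ids <- setdiff(protein_ids, ribosomal_filter)
  }
  for (pid in protein_ids) {
    assigned <- cog_map[[pid]]
    if (is.null(assigned) || !length(assigned)) assigned <- "-"
    for (a in assigned) counts[[a]] <- counts[[a]] + 1L
  }
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * 0
  structure(list(counts = counts, fractions = fractions,
                 n_assignments = total),
            class = "cog_distribution")
}

#' @export
print.cog_distribution <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("COG distribution:", x$n_assignments, "assignments over",
      length(nz), "categories\n")
  if (length(nz)) print(nz)
  invisible(x)
}

#' Compare COG distributions of paralogs, singletons and a reference set
#'
#' Produces a per-category table of the three fractions plus the log2
#' ratio paralogs/singletons. Because the relative scaling of the two
#' groups is sensitive (e.g. to ribosomal-protein handling), categories
#' where one group is essentially absent while the other is clearly
#' present are flagged as dominated: fraction < eps on one side and
#' >= 5 * eps on the other.
#'
#' @param paralogs,singletons,reference `cog_distribution` objects.
#' @param eps Domination threshold on assignment fractions.
#' @return Data frame: category, paralog_fraction, singleton_fraction,
#'   reference_fraction, log2_ratio, flag (`""`, `"paralog-dominated"` or
#'   `"singleton-dominated"`).
#' @export
compare_distributions <- function(paralogs, singletons, reference,
                                  eps = 0.005) {
  stopifnot(inherits(paralogs, "cog_distribution"),
            inherits(singletons, "cog_distribution"),
            inherits(reference, "cog_distribution"))
  cats <- names(paralogs$fractions)
  pf <- paralogs$fractions
  sf <- singletons$fractions
  rf <- reference$fractions
  flag <- rep("", length(cats))
  flag[pf >= 5 * eps & sf < eps] <- "paralog-dominated"
  flag[sf >= 5 * eps & pf < eps] <- "singleton-dominated"
  data.frame(category = cats,
             paralog_fraction = unname(pf),
             singleton_fraction = unname(sf),
             reference_fraction = unname(rf),
             log2_ratio = unname(log2(pf / sf)),
             flag = flag,
             stringsAsFactors = FALSE)
}

#' @noRd
plurality_category <- function(protein_ids, cog_map) {
  dist <- cog_distribution(protein_ids, cog_map)
  counts <- dist$counts[dist$counts > 0]
  if (!length(counts)) {
    return(list(category = "-", support = 1, tied = FALSE, total = 0L))
  }
  top <- max(counts)
  winners <- sort(names(counts)[counts == top])
  list(category = winners[[1]],
       support = top / dist$n_assignments,
       tied = length(winners) > 1L,
       total = dist$n_assignments)
}

#' Consensus COG category of a cluster of paralogs
#'
#' Plurality vote over all category assignments of the cluster's
#' paralogs; ties are broken by the lexicographically smallest letter and
#' flagged. Support is the winning count over total assignments.
#'
#' @param cluster_paralog_ids Protein IDs in the cluster (non-empty).
#' @param cog_map Named list protein ID -> categories.
#' @return List: category, support, tied.
#' @export
consensus_cog <- function(cluster_paralog_ids, cog_map) {
  stopifnot(length(cluster_paralog_ids) >= 1L)
  res <- plurality_category(cluster_paralog_ids, cog_map)
  res[c("category", "support", "tied")]
}

#' COG category of a single ontology term's member paralogs
#'
#' Same plurality rule applied at the term level; the result may differ
#' from the cluster-level consensus, and both are reported unchanged.
#'
#' @param term Term ID (carried through to the result).
#' @param member_paralogs Protein IDs annotated with the term.
#' @param cog_map Named list protein ID -> categories.
#' @return List: term, category, support, tied.
#' @export
per_term_cog <- function(term, member_paralogs, cog_map) {
  stopifnot(length(member_paralogs) >= 1L)
  res <- plurality_category(member_paralogs, cog_map)
  c(list(term = term), res[c("category", "support", "tied")])
}
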