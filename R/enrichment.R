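#' One-sided Fisher (hypergeometric tail) overrepresentation p-value
#'
#' Probability of observing `k` or more study hits in a 2x2 table with
#' study size `n`, background hits `K` and background size `N`:
#' p = sum_{i = k}^{min(n, K)} C(K, i) C(N - K, n - i) / C(N, n).
#'
#' @param k Study hits.
#' @param n Study size.
#' @param K Background hits.
#' @param N Background size.
#' @param ease Use the conservative EASE variant (one study hit removed,
#'   i.e. the tail from `k - 1`)?
#' @return The one-sided p-value. Vectorized over the four counts.
#' @export
fisher_p <- function(k, n, K, N, ease = FALSE) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("negative count")
  if (any(k > n)) stop("k must be <= n")
  if (any(n > N)) stop("n must be <= N")
  if (any(K > N)) stop("K must be <= N")
  if (any(k > K)) stop("k must be <= K")
  kk <- if (ease) pmax(k - 1, 0) else k
  stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assemble a background model for overrepresentation analysis
#'
#' The three models the pipeline supports: `all_paralogs` (the union of
#' every organism's paranome), `all_proteomes` (every protein of every
#' organism) and `individual_proteome` (the tested organism's own
#' proteome). For `all_paralogs` and `individual_proteome` the study set
#' is a subset of the background by construction.
#'
#' @param kind One of `"all_paralogs"`, `"all_proteomes"`,
#'   `"individual_proteome"`.
#' @param proteomes List of `proteome` objects.
#' @param paranomes Named list organism ID -> paralog protein IDs.
#' @param organism_id Organism under test (needed for
#'   `individual_proteome`).
#' @return List: kind, member protein IDs.
#' @export
background_model <- function(kind = c("all_paralogs", "all_proteomes",
                                      "individual_proteome"),
                             proteomes, paranomes, organism_id = NULL) {
  kind <- match.arg(kind)
  members <- switch(kind,
    all_paralogs = sort(unique(unlist(paranomes, use.names = FALSE))),
    all_proteomes = sort(unique(unlist(lapply(proteomes, function(p)
      names(p$proteins)), use.names = FALSE))),
    individual_proteome = {
      if (is.null(organism_id)) stop("organism_id required")
      hit <- Filter(function(p) p$organism_id == organism_id, proteomes)
      if (!length(hit)) stop("unknown organism: ", organism_id)
      sort(names(hit[[1]]$proteins))
    })
  list(kind = kind, members = members)
}

#' Per-organism overrepresentation analysis of paranome annotations
#'
#' Tests every ontology term annotated to at least one study protein
#' against the background with a one-sided Fisher test and applies
#' Bonferroni correction over that organism's tested-term count. Only
#' terms with corrected significance below `alpha` are returned.
#' Annotations must already be ancestor-closed (see [propagate()]); each
#' protein counts at most once per term.
#'
#' @param paranome A `paranome` object or character vector of study
#'   protein IDs.
#' @param background A background model from [background_model()] or a
#'   character vector of protein IDs.
#' @param annotations Named list protein ID -> propagated term IDs
#'   (covering study and background proteins).
#' @param alpha Bonferroni-corrected significance cutoff.
#' @param organism_id Organism label on the output records.
#' @param ease Use the EASE score variant of the Fisher test?
#' @return Data frame of enrichment records: organism, term, k, n, K, N,
#'   m (tested terms), p_raw, p_bonferroni; rows sorted by p then term.
#' @export
enrich_organism <- function(paranome, background, annotations, alpha = 0.01,
                            organism_id = NULL, ease = FALSE) {
  if (inherits(paranome, "paranome")) {
    if (is.null(organism_id)) organism_id <- paranome$organism_id
    study <- paranome$paralog_ids
  } else {
    study <- as.character(paranome)
  }
  if (is.null(organism_id)) organism_id <- "organism"
  bg <- if (is.list(background)) background$members else
    as.character(background)
  empty <- data.frame(organism = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), m = integer(0), p_raw = numeric(0),
                      p_bonferroni = numeric(0), stringsAsFactors = FALSE)
  if (!length(study)) {
    warning("empty paranome for ", organism_id)
    return(empty)
  }
  study <- sort(unique(study))
  bg <- sort(unique(bg))
  n <- length(study)
  N <- length(bg)
  study_terms <- annotations[study]
  bg_terms <- annotations[bg]
  k_tab <- table(unlist(lapply(study_terms, unique), use.names = FALSE))
  if (!length(k_tab)) return(empty)
  K_tab <- table(unlist(lapply(bg_terms, unique), use.names = FALSE))
  terms <- sort(names(k_tab))
  m <- length(terms)
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  K[is.na(K)] <- 0L
  p_raw <- fisher_p(k, n, K, N, ease = ease)
  p_bonf <- pmin(1, p_raw * m)
  res <- data.frame(organism = organism_id, term = terms, k = k, n = n,
                    K = K, N = N, m = m, p_raw = p_raw,
                    p_bonferroni = p_bonf, stringsAsFactors = FALSE)
  res <- res[res$p_bonferroni < alpha, , drop = FALSE]
  res <- res[order(res$p_bonferroni, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep only terms found overrepresented in several organisms
#'
#' A term survives only if it appears (after Bonferroni filtering) in at
#' least `min_organisms` distinct organisms; removal is applied to every
#' organism's record list.
#'
#' @param per_organism_results Data frame of enrichment records pooled
#'   over organisms (rbind of [enrich_organism()] outputs).
#' @param min_organisms Minimum distinct organisms per term.
#' @return The filtered record data frame.
#' @export
cross_organism_filter <- function(per_organism_results, min_organisms = 3) {
  stopifnot(is.data.frame(per_organism_results))
  if (!nrow(per_organism_results)) return(per_organism_results)
  n_org <- tapply(per_organism_results$organism,
                  per_organism_results$term,
                  function(x) length(unique(x)))
  keep_terms <- names(n_org)[n_org >= min_organisms]
  out <- per_organism_results[per_organism_results$term %in% keep_terms, ,
                              drop = FALSE]
  rownames(out) <- NULL
  out
}
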