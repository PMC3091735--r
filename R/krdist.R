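#' Shortest-unique-substring profile of a query against a subject
#'
#' For each position i of the query, reports the length of the shortest
#' prefix of the suffix starting at i that does not occur as a substring
#' of the subject, computed exactly (a suffix automaton of the subject
#' provides the longest-match statistic; the shortest absent prefix is
#' one longer). When the entire remaining suffix occurs in the subject
#' the value is remaining length + 1 by convention.
#'
#' @param query,subject DNA strings (alphabet ACGT; other symbols are
#'   stripped with a warning). Both must be at least 100 bases long.
#' @return Integer vector, one value per query position.
#' @export
shulen_profile <- function(query, subject) {
  query <- clean_dna(query, "query")
  subject <- clean_dna(subject, "subject")
  if (nchar(query) < 100 || nchar(subject) < 100) {
    stop("sequences must be at least 100 bases after cleaning")
  }
  .match_lengths_from(query, subject) + 1L
}

#' @noRd
clean_dna <- function(x, what) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  cleaned <- gsub("[^ACGT]", "", x)
  if (nchar(cleaned) < nchar(x)) {
    warning(nchar(x) - nchar(cleaned), " non-ACGT symbol(s) stripped from ",
            what)
  }
  if (!nchar(cleaned)) stop(what, " is empty after removing non-ACGT symbols")
  cleaned
}

#' Expected longest-match statistic under divergence p
#'
#' For a query position, the longest match against the subject is the
#' maximum of the homologous run (P(run >= L) = (1-p)^L under site-wise
#' mismatch probability p) and the best background match anywhere in a
#' subject of m sites (P(>= L) ~ 1 - (1 - 4^-L)^m). Assuming
#' independence, E[ms] = sum_L P(max >= L). This is the calibration curve
#' the distance estimator inverts; at p near the Jukes-Cantor ceiling of
#' 3/4 it saturates at the null (unrelated-sequence) expectation.
#' @noRd
expected_match_stat <- function(p, m, lmax_cap = 250000L) {
  q <- 1 - p
  lmax <- if (q >= 1) lmax_cap else
    min(lmax_cap, max(60L, ceiling(log(1e-13) / log(q))))
  L <- seq_len(lmax)
  b <- -expm1(m * log1p(-(4^(-L))))    # P(background match >= L)
  sum(b + q^L * (1 - b))
}

#' Alignment-free evolutionary distance between two DNA sequences
#'
#' Estimates substitutions per site from the mean shortest-unique-
#' substring statistic: the observed mean longest-match length is
#' inverted through its expectation under site-wise mismatch probability
#' p (calibrated against the null expectation for unrelated sequences of
#' the given lengths), and p is then Jukes-Cantor corrected,
#' d = -3/4 log(1 - 4p/3). The two directed estimates are averaged so
#' the distance is symmetric. Pairs whose match statistic is not
#' distinguishable from the unrelated-sequence null are flagged
#' saturated and capped just below the Jukes-Cantor ceiling.
#'
#' @param a,b DNA strings (ACGT).
#' @param p_min,p_max Bracketing interval for the mismatch estimate; the
#'   upper bound sits just under the Jukes-Cantor limit of 3/4.
#' @return Distance in substitutions/site with attributes `saturated`
#'   (logical) and `p_hat` (mismatch estimate). Identical sequences give
#'   exactly 0. Sequences shorter than 1 kb trigger a wide-uncertainty
#'   warning.
#' @export
kr_distance <- function(a, b, p_min = 1e-5, p_max = 0.7499) {
  a <- clean_dna(a, "a")
  b <- clean_dna(b, "b")
  if (identical(a, b)) {
    return(structure(0, saturated = FALSE, p_hat = 0))
  }
  if (nchar(a) < 1000 || nchar(b) < 1000) {
    warning("sequences shorter than 1 kb: distance estimate has wide ",
            "uncertainty")
  }
  est_dir <- function(q, s) {
    prof <- shulen_profile(q, s) - 1  # back to match-statistic scale
    obs <- mean(prof)
    m <- nchar(s)
    # Saturation: flag when the observed statistic is statistically
    # indistinguishable from the unrelated-sequence null. Positions
    # within one match run are correlated, so the effective sample size
    # is deflated by the mean run length.
    e0 <- expected_match_stat(p_max, m)
    n_eff <- length(prof) / (obs + 1)
    se <- stats::sd(prof) / sqrt(n_eff)
    if (obs <= e0 + 3 * se) return(list(p = p_max, saturated = TRUE))
    f <- function(p) expected_match_stat(p, m) - obs
    if (f(p_min) <= 0) return(list(p = p_min, saturated = FALSE))
    root <- stats::uniroot(f, c(p_min, p_max), tol = 1e-7)
    list(p = root$root, saturated = FALSE)
  }
  d1 <- est_dir(a, b)
  d2 <- est_dir(b, a)
  p_hat <- (d1$p + d2$p) / 2
  saturated <- d1$saturated || d2$saturated
  if (saturated) p_hat <- p_max
  d <- -0.75 * log(1 - 4 * p_hat / 3)
  structure(d, saturated = saturated, p_hat = p_hat)
}

#' Pairwise alignment-free distance matrix
#'
#' Runs [kr_distance()] on every organism pair. Organisms with a missing
#' (NULL or NA) sequence are dropped with a warning.
#'
#' @param sequences Named character vector or list, organism ID -> DNA
#'   sequence (the caller selects one 16S sequence per genome).
#' @return Symmetric numeric matrix (zero diagonal) with organism IDs as
#'   dimnames; attribute `saturated_pairs` lists flagged pairs.
#' @export
distance_matrix <- function(sequences) {
  if (is.list(sequences)) {
    missing <- names(sequences)[vapply(sequences, function(s)
      is.null(s) || all(is.na(s)), logical(1))]
    sequences <- unlist(Filter(function(s) !is.null(s) && !all(is.na(s)),
                               sequences))
  } else {
    missing <- names(sequences)[is.na(sequences)]
    sequences <- sequences[!is.na(sequences)]
  }
  if (length(missing)) {
    warning("organism(s) without a sequence dropped: ",
            paste(missing, collapse = ", "))
  }
  stopifnot(length(sequences) >= 2L, !is.null(names(sequences)))
  orgs <- sort(names(sequences))
  n <- length(orgs)
  d <- matrix(0, n, n, dimnames = list(orgs, orgs))
  sat <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- kr_distance(sequences[[orgs[i]]], sequences[[orgs[j]]])
      d[i, j] <- d[j, i] <- as.numeric(dij)
      if (isTRUE(attr(dij, "saturated"))) {
        sat[[length(sat) + 1L]] <- c(orgs[i], orgs[j])
      }
    }
  }
  attr(d, "saturated_pairs") <- sat
  d
}

#' Mean pairwise phylogenetic distance within a bicluster
#'
#' @param bicluster A bicluster (list with `rows`) or a character vector
#'   of organism IDs.
#' @param dmat Distance matrix from [distance_matrix()].
#' @param method `"mean"` (default) or `"max"` over unordered pairs.
#' @return Numeric cluster-level distance (0 for a single organism).
#' @export
cluster_distance <- function(bicluster, dmat, method = c("mean", "max")) {
  method <- match.arg(method)
  orgs <- if (is.list(bicluster)) bicluster$rows else as.character(bicluster)
  absent <- setdiff(orgs, rownames(dmat))
  if (length(absent)) {
    stop("organism(s) absent from distance matrix: ",
         paste(absent, collapse = ", "))
  }
  if (length(orgs) < 2L) return(0)
  sub <- dmat[orgs, orgs]
  vals <- sub[upper.tri(sub)]
  if (method == "mean") mean(vals) else max(vals)
}

#' Select candidate convergent-adaptation clusters
#'
#' Keeps biclusters whose functional homogeneity and phylogenetic
#' divergence both exceed strict cutoffs (similarity > `sim_cut` and
#' distance > `dist_cut`). With `dedup = TRUE`, among selected clusters
#' with overlapping organism sets only the one with fewest organisms is
#' kept (ties: fewest terms, then lexicographic row set).
#'
#' @param cluster_scores Data frame with columns `cluster_id`,
#'   `go_similarity`, `phylo_distance`.
#' @param biclusters Named (by `cluster_id`) or index-aligned list of
#'   biclusters supplying the organism/term sets.
#' @param sim_cut,dist_cut Strict lower cutoffs.
#' @param dedup Deduplicate overlapping selected clusters?
#' @return Data frame of convergence calls: cluster_id, go_similarity,
#'   phylo_distance, n_organisms, n_terms, selected (logical; after
#'   deduplication).
#' @export
select_convergent <- function(cluster_scores, biclusters, sim_cut = 0.7,
                              dist_cut = 0.1, dedup = TRUE) {
  stopifnot(all(c("cluster_id", "go_similarity", "phylo_distance") %in%
                  names(cluster_scores)))
  df <- cluster_scores
  bc <- biclusters
  if (is.null(names(bc))) names(bc) <- as.character(seq_along(bc))
  df$n_organisms <- vapply(df$cluster_id,
                           function(i) length(bc[[as.character(i)]]$rows), 0L)
  df$n_terms <- vapply(df$cluster_id,
                       function(i) length(bc[[as.character(i)]]$cols), 0L)
  df$selected <- df$go_similarity > sim_cut & df$phylo_distance > dist_cut
  if (dedup && any(df$selected)) {
    sel <- which(df$selected)
    key <- vapply(df$cluster_id[sel], function(i)
      paste(bc[[as.character(i)]]$rows, collapse = ","), "")
    ord <- sel[order(df$n_organisms[sel], df$n_terms[sel], key)]
    kept <- integer(0)
    for (i in ord) {
      rows_i <- bc[[as.character(df$cluster_id[i])]]$rows
      overlaps <- any(vapply(kept, function(j) {
        length(intersect(rows_i,
                         bc[[as.character(df$cluster_id[j])]]$rows)) > 0
      }, logical(1)))
      if (overlaps) df$selected[i] <- FALSE else kept <- c(kept, i)
    }
  }
  rownames(df) <- NULL
  df
}
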