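# Karlin-Altschul parameters for BLOSUM62 with affine gaps 11/1
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' All-vs-all within-proteome similarity search
#'
#' Performs exhaustive pairwise local alignment (Smith-Waterman via
#' dynamic programming, BLOSUM62, affine gap penalties 11/1) of every
#' protein pair in one proteome and reports hits passing an E-value
#' threshold. E-values follow the Karlin-Altschul model with the database
#' size set to the proteome's total residue count (the search is
#' within-proteome). Percent identity is computed over the aligned columns
#' of the local alignment (matches / alignment length x 100). Self-hits
#' are excluded; both hit directions are reported.
#'
#' @param proteome A `proteome` object.
#' @param evalue_max Maximum E-value for a reported hit.
#' @param max_hits Maximum number of subject hits kept per query.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Data frame with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `evalue` (BLAST tabular naming), ordered by query then E-value.
#' @export
all_vs_all <- function(proteome, evalue_max = 1e-5, max_hits = 1000,
                       gap_opening = 11, gap_extension = 1) {
  stopifnot(inherits(proteome, "proteome"))
  seqs <- proteome$proteins
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(bad)) {
    stop("sequence with illegal characters: ",
         paste(head(names(seqs)[bad], 5), collapse = ", "))
  }
  n <- length(seqs)
  empty <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  aa <- Biostrings::AAStringSet(seqs)
  db_size <- sum(nchar(seqs))
  lens <- nchar(seqs)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub_mat <- get("BLOSUM62", envir = environment())

  out <- list()
  for (i in seq_len(n - 1L)) {
    subjects <- seq.int(i + 1L, n)
    aln <- Biostrings::pairwiseAlignment(
      pattern = aa[subjects], subject = aa[[i]], type = "local",
      substitutionMatrix = sub_mat,
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    score <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    pident <- 100 * Biostrings::nmatch(aln) / alen
    # E-value per direction: query length x database residues
    e_fwd <- KA_K * lens[i] * db_size * exp(-KA_LAMBDA * score)
    e_rev <- KA_K * lens[subjects] * db_size * exp(-KA_LAMBDA * score)
    keep <- e_fwd <= evalue_max | e_rev <= evalue_max
    if (any(keep)) {
      js <- subjects[keep]
      out[[length(out) + 1L]] <- data.frame(
        qseqid = c(rep(names(seqs)[i], length(js)), names(seqs)[js]),
        sseqid = c(names(seqs)[js], rep(names(seqs)[i], length(js))),
        pident = rep(pident[keep], 2L),
        length = rep(alen[keep], 2L),
        evalue = c(e_fwd[keep], e_rev[keep]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits <- hits[order(hits$qseqid, hits$evalue, hits$sseqid), , drop = FALSE]
  # per-query hit cap (mirrors the BLAST max-hits setting)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$qseqid),
                        function(ix) head(ix, max_hits)), use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Call paralogs from a hit table at an identity threshold
#'
#' A protein is a paralog if it appears in at least one within-proteome
#' hit at or above the identity threshold; the number of copies is not
#' counted. The paralog fraction (degree of duplication) is the number of
#' paralog-forming proteins over the proteome size.
#'
#' @param hits Hit table from [all_vs_all()] for one organism.
#' @param proteome The `proteome` the hits came from.
#' @param identity_threshold Percent identity cutoff (default 75).
#' @return An object of class `paranome`: organism_id, paralog_ids
#'   (sorted), paralog_fraction, n_proteins.
#' @export
call_paralogs <- function(hits, proteome, identity_threshold = 75) {
  stopifnot(inherits(proteome, "proteome"))
  sel <- hits[hits$pident >= identity_threshold, , drop = FALSE]
  ids <- sort(unique(c(sel$qseqid, sel$sseqid)))
  unknown <- setdiff(ids, names(proteome$proteins))
  if (length(unknown)) {
    stop("hit table references proteins not in proteome: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  structure(list(organism_id = proteome$organism_id,
                 paralog_ids = ids,
                 paralog_fraction = length(ids) / length(proteome$proteins),
                 n_proteins = length(proteome$proteins)),
            class = "paranome")
}

#' @export
print.paranome <- function(x, ...) {
  cat("paranome", x$organism_id, ":", length(x$paralog_ids), "/",
      x$n_proteins, sprintf("proteins (fraction %.4f)\n", x$paralog_fraction))
  invisible(x)
}

#' Rank organisms by paralog fraction
#'
#' Descending by fraction; ties are broken lexicographically by organism
#' ID and flagged.
#'
#' @param paranomes List of `paranome` objects.
#' @param top_n Number of organisms to keep (warns and returns all if
#'   fewer are available).
#' @return Data frame: organism_id, n_paralogs, n_proteins,
#'   paralog_fraction, tied.
#' @export
paralog_fraction_rank <- function(paranomes, top_n = 200) {
  stopifnot(length(paranomes) >= 1L)
  df <- data.frame(
    organism_id = vapply(paranomes, `[[`, "", "organism_id"),
    n_paralogs = vapply(paranomes, function(p) length(p$paralog_ids), 0L),
    n_proteins = as.integer(vapply(paranomes, `[[`, 0, "n_proteins")),
    paralog_fraction = vapply(paranomes, `[[`, 0, "paralog_fraction"),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$paralog_fraction, df$organism_id), , drop = FALSE]
  df$tied <- duplicated(df$paralog_fraction) |
    duplicated(df$paralog_fraction, fromLast = TRUE)
  if (top_n > nrow(df)) {
    warning("top_n (", top_n, ") exceeds available organisms (", nrow(df),
            "); returning all")
    top_n <- nrow(df)
  }
  out <- head(df, top_n)
  rownames(out) <- NULL
  out
}

#' Fit the paralog-count versus genome-size trend
#'
#' Ordinary least squares of number-of-paralog-genes on genome size (Mb),
#' with Pearson correlation. With `outlier_policy = "flag"`, points whose
#' absolute studentized residual exceeds 3 are flagged and a second fit
#' excluding them is reported.
#'
#' @param points Data frame with columns `genome_mb` and `n_paralogs`
#'   (optionally `organism_id` for labelling outliers).
#' @param outlier_policy `"flag"` (default) or `"none"`.
#' @return List of class `trend_fit`: slope, intercept, pearson_r,
#'   outlier_ids, and (when flagging finds outliers) `fit_excluding` with
#'   the refit slope/intercept/r.
#' @export
fit_trend <- function(points, outlier_policy = c("flag", "none")) {
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(all(c("genome_mb", "n_paralogs") %in% names(points)),
            nrow(points) >= 3L)
  if (stats::sd(points$genome_mb) == 0) {
    stop("zero variance in genome size; trend undefined")
  }
  ids <- if ("organism_id" %in% names(points)) points$organism_id else
    as.character(seq_len(nrow(points)))
  fit <- stats::lm(n_paralogs ~ genome_mb, data = points)
  r <- stats::cor(points$genome_mb, points$n_paralogs)
  outliers <- character(0)
  fit_ex <- NULL
  if (outlier_policy == "flag") {
    rs <- stats::rstudent(fit)
    outliers <- ids[is.finite(rs) & abs(rs) > 3]
    if (length(outliers)) {
      keep <- !(ids %in% outliers)
      sub <- points[keep, , drop = FALSE]
      fit2 <- stats::lm(n_paralogs ~ genome_mb, data = sub)
      fit_ex <- list(slope = unname(coef(fit2)[2]),
                     intercept = unname(coef(fit2)[1]),
                     pearson_r = stats::cor(sub$genome_mb, sub$n_paralogs))
    }
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r,
                 outlier_ids = outliers,
                 fit_excluding = fit_ex),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: y = %.2fx + %.2f (r = %.3f)\n",
              x$slope, x$intercept, x$pearson_r))
  if (length(x$outlier_ids)) {
    cat("outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    cat(sprintf("excluding outliers: y = %.2fx + %.2f (r = %.3f)\n",
                x$fit_excluding$slope, x$fit_excluding$intercept,
                x$fit_excluding$pearson_r))
  }
  invisible(x)
}
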