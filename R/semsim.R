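#' Semantic value of an ontology term (Wang measure)
#'
#' Encodes a term's biological meaning by aggregating edge-weighted
#' contributions of its ancestors: the term itself contributes S = 1, and
#' an ancestor t contributes S(t) = max over its children c inside the
#' term's ancestor graph of w(edge) * S(c), with w = 0.8 for `is_a` and
#' 0.6 for `part_of` by default. The semantic value of the term is the
#' sum of all contributions.
#'
#' @param term A term ID in the DAG.
#' @param dag An `onto_dag`.
#' @param weights Named numeric vector of edge weights per relation.
#' @return Object of class `semantic_value`: `term`, `s_values` (named
#'   contributions, including the term itself at 1) and `sv_total`.
#' @export
semantic_value <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  t0 <- dag_resolve(dag, term)
  if (is.na(t0)) stop("unknown term: ", term)
  anc <- dag_ancestors(dag, t0, include_self = TRUE)
  memo <- new.env(parent = emptyenv())
  assign(t0, 1, envir = memo)
  svalue <- function(t) {
    got <- get0(t, envir = memo, ifnotfound = NULL)
    if (!is.null(got)) return(got)
    # children of t within the ancestor graph
    rows <- which(dag$edges$parent == t & dag$edges$child %in% anc)
    vals <- vapply(rows, function(r) {
      unname(weights[[dag$edges$relation[r]]]) * svalue(dag$edges$child[r])
    }, numeric(1))
    v <- max(vals)
    assign(t, v, envir = memo)
    v
  }
  s <- vapply(anc, svalue, numeric(1))
  structure(list(term = t0, s_values = s, sv_total = sum(s)),
            class = "semantic_value")
}

#' Wang similarity between two ontology terms
#'
#' sim(a, b) = sum over shared ancestors t of (S_a(t) + S_b(t)) divided
#' by (SV(a) + SV(b)). Terms from different namespaces score 0.
#'
#' @param a,b Term IDs.
#' @param dag An `onto_dag`.
#' @param weights Edge weights per relation.
#' @return Similarity in [0, 1].
#' @export
term_similarity <- function(a, b, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  ra <- dag_resolve(dag, a)
  rb <- dag_resolve(dag, b)
  if (is.na(ra)) stop("unknown term: ", a)
  if (is.na(rb)) stop("unknown term: ", b)
  if (dag$namespaces[[ra]] != dag$namespaces[[rb]]) return(0)
  sa <- semantic_value(ra, dag, weights)
  sb <- semantic_value(rb, dag, weights)
  shared <- intersect(names(sa$s_values), names(sb$s_values))
  if (!length(shared)) return(0)
  sum(sa$s_values[shared] + sb$s_values[shared]) /
    (sa$sv_total + sb$sv_total)
}

#' Mean within-cluster term similarity
#'
#' The homogeneity score of a bicluster: the mean Wang similarity over
#' all unordered distinct term pairs in the cluster's column set. A
#' single-term cluster scores 1 and is flagged as a singleton. Pairs from
#' different namespaces contribute 0, penalizing mixed clusters.
#'
#' @param terms Character vector of term IDs (a bicluster's columns), or
#'   a bicluster list with a `cols` element.
#' @param dag An `onto_dag`.
#' @param weights Edge weights per relation.
#' @param include_self_pairs Also average in the k self-similarities
#'   (always 1 each)? Off by default.
#' @return Numeric score in [0, 1]; attribute `singleton` marks
#'   single-term clusters.
#' @export
cluster_similarity <- function(terms, dag,
                               weights = c(is_a = 0.8, part_of = 0.6),
                               include_self_pairs = FALSE) {
  if (is.list(terms) && !is.null(terms$cols)) terms <- terms$cols
  terms <- unique(as.character(terms))
  stopifnot(length(terms) >= 1L)
  if (length(terms) == 1L) {
    return(structure(1, singleton = TRUE))
  }
  pairs <- utils::combn(terms, 2L)
  sims <- vapply(seq_len(ncol(pairs)), function(i) {
    term_similarity(pairs[1, i], pairs[2, i], dag, weights)
  }, numeric(1))
  if (include_self_pairs) sims <- c(sims, rep(1, length(terms)))
  structure(mean(sims), singleton = FALSE)
}

#' Compare within-cluster similarity scores across background models
#'
#' Box-plot statistics per model (mean, median, quartiles) and Welch
#' two-sided t-tests for every model pair; the model with the highest
#' mean score is identified. Models with fewer than two scores are
#' excluded with a warning.
#'
#' @param scores_by_model Named list model -> numeric vector of cluster
#'   similarity scores.
#' @return List: `summary` (data frame model, n, mean, median, q1, q3),
#'   `pairwise` (data frame model_a, model_b, p_value), `best_model`.
#' @export
compare_backgrounds <- function(scores_by_model) {
  stopifnot(is.list(scores_by_model), !is.null(names(scores_by_model)))
  sizes <- lengths(scores_by_model)
  if (any(sizes < 2)) {
    warning("model(s) with < 2 scores excluded: ",
            paste(names(scores_by_model)[sizes < 2], collapse = ", "))
    scores_by_model <- scores_by_model[sizes >= 2]
  }
  stopifnot(length(scores_by_model) >= 1L)
  models <- names(scores_by_model)
  summ <- do.call(rbind, lapply(models, function(m) {
    x <- scores_by_model[[m]]
    data.frame(model = m, n = length(x), mean = mean(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pw <- NULL
  if (length(models) >= 2L) {
    cmb <- utils::combn(models, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- scores_by_model[[cmb[1, i]]]
      b <- scores_by_model[[cmb[2, i]]]
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)$p.value
      }
      data.frame(model_a = cmb[1, i], model_b = cmb[2, i], p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, pairwise = pw,
       best_model = summ$model[which.max(summ$mean)])
}
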