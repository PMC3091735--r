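# Independent oracles the implementation is checked against.

# Naive longest-match statistic: for each query position, grow the
# substring until it no longer occurs in the subject (fixed-string search).
naive_match_stat <- function(q, s) {
  n <- nchar(q)
  vapply(seq_len(n), function(i) {
    l <- 0L
    while (i + l <= n && grepl(substr(q, i, i + l), s, fixed = TRUE)) {
      l <- l + 1L
    }
    l
  }, integer(1))
}

# Exhaustive hypergeometric tail by direct summation of binomial products.
fisher_oracle <- function(k, n, K, N) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force inclusion-maximal all-ones submatrices via closure of every
# row subset (feasible for <= ~12 rows).
brute_force_biclusters <- function(mat, min_rows = 2, min_cols = 2) {
  nr <- nrow(mat)
  res <- list()
  seen <- character(0)
  for (mask in seq_len(2^nr - 1)) {
    rows <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nr) - 1L)) != 0L)
    cols <- which(colSums(mat[rows, , drop = FALSE]) == length(rows))
    if (!length(cols)) next
    crows <- which(rowSums(mat[, cols, drop = FALSE]) == length(cols))
    key <- paste(paste(crows, collapse = ","), paste(cols, collapse = ";"))
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(crows) >= min_rows && length(cols) >= min_cols) {
      res[[length(res) + 1L]] <- list(rows = sort(rownames(mat)[crows]),
                                      cols = sort(colnames(mat)[cols]))
    }
  }
  res
}

canonical_biclusters <- function(bcs) {
  sort(vapply(bcs, function(b) {
    paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","),
          sep = "|")
  }, character(1)))
}

# Brute-force Wang S-values: best product of edge weights over every
# directed path from the term to each ancestor.
wang_oracle_svalues <- function(term, dag, weights = c(is_a = 0.8,
                                                       part_of = 0.6)) {
  best <- new.env(parent = emptyenv())
  dfs <- function(node, val) {
    prev <- get0(node, envir = best, ifnotfound = -Inf)
    if (val > prev) assign(node, val, envir = best)
    rows <- which(dag$edges$child == node)
    for (r in rows) {
      dfs(dag$edges$parent[r], val * weights[[dag$edges$relation[r]]])
    }
  }
  dfs(term, 1)
  vals <- mget(ls(best), envir = best)
  unlist(vals)
}

wang_oracle_similarity <- function(a, b, dag,
                                   weights = c(is_a = 0.8, part_of = 0.6)) {
  if (dag$namespaces[[a]] != dag$namespaces[[b]]) return(0)
  sa <- wang_oracle_svalues(a, dag, weights)
  sb <- wang_oracle_svalues(b, dag, weights)
  shared <- intersect(names(sa), names(sb))
  if (!length(shared)) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# Alignment-based Jukes-Cantor distance for gap-free simulated sequences.
jc_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  p <- mean(x != y)
  -0.75 * log(1 - 4 * p / 3)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# Tiny proteome with uniform dummy sequences, for annotation/enrichment
# fixtures where the sequences themselves are never aligned.
dummy_proteome <- function(org, n_proteins, genome_size = 2e6) {
  ids <- sprintf("%s_p%03d", org, seq_len(n_proteins))
  seqs <- stats::setNames(rep(strrep("MKVLA", 8), n_proteins), ids)
  proteome(org, seqs, genome_size)
}

chain_dag <- function() {
  onto_dag(c("a", "b", "c"),
           data.frame(child = c("b", "c"), parent = c("a", "b"),
                      relation = "is_a", stringsAsFactors = FALSE))
}
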