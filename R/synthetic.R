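AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a proteome object
#'
#' @param organism_id Unique organism identifier.
#' @param proteins Named character vector of amino-acid sequences
#'   (alphabet: the 20 standard residues plus X).
#' @param genome_size Genome length in base pairs (main chromosome).
#' @param species_label,strain_label Taxonomic labels.
#' @param cog Named list protein ID -> character vector of COG category
#'   letters (possibly empty); defaults to no assignments.
#' @return An object of class `proteome`.
#' @export
proteome <- function(organism_id, proteins, genome_size,
                     species_label = organism_id, strain_label = "",
                     cog = NULL) {
  stopifnot(is.character(proteins), length(proteins) >= 1L,
            !is.null(names(proteins)))
  if (anyDuplicated(names(proteins))) {
    stop("duplicate protein IDs in proteome ", organism_id)
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", proteins)
  if (any(bad)) {
    stop("protein(s) with illegal characters or empty sequence: ",
         paste(head(names(proteins)[bad], 5), collapse = ", "))
  }
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be positive")
  }
  if (is.null(cog)) {
    cog <- rep(list(character(0)), length(proteins))
    names(cog) <- names(proteins)
  }
  structure(list(organism_id = organism_id,
                 species_label = species_label,
                 strain_label = strain_label,
                 proteins = proteins,
                 cog = cog,
                 genome_size = as.numeric(genome_size)),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome", x$organism_id, "(", x$species_label, "):",
      length(x$proteins), "proteins,", x$genome_size, "bp\n")
  invisible(x)
}

#' Per-site substitution probability giving a target expected pairwise identity
#'
#' Two family members are derived independently from a common ancestor by
#' point substitutions (uniform over the 19 alternative residues). With
#' per-site substitution probability s the expected pairwise identity is
#' (1-s)^2 + s^2/19; this solves for s.
#' @noRd
identity_to_subst_rate <- function(target_identity) {
  a <- 20 / 19
  disc <- 1 - a * (1 - target_identity)
  if (disc < 0) return(1)  # below the floor reachable by substitutions only
  (1 - sqrt(disc)) / a
}

#' Generate a synthetic proteome with planted paralog families
#'
#' Each family is built by mutating a random ancestor sequence with point
#' substitutions only (uniform across positions and across the 19
#' alternative residues), calibrated so the expected pairwise identity
#' within the family equals `target_identity`. Singletons are independent
#' uniform-random sequences, hence mutually unrelated (~5% identity).
#'
#' @param family_specs List of family specifications; each a list with
#'   elements `size` (members, >= 1), `identity` (target pairwise identity
#'   in (0,1]), `length` (protein length, >= 30), and optionally `cog`
#'   (a COG category letter) and `terms` (ontology term IDs carried as the
#'   family's annotation payload in the truth table).
#' @param n_singletons Number of unrelated background proteins.
#' @param genome_size Genome length in bp recorded on the proteome.
#' @param seed RNG seed (required; the generator is a pure function of its
#'   parameters and the seed).
#' @param organism_id,species_label,strain_label Identifiers.
#' @param singleton_length Length of singleton proteins.
#' @return List with elements `proteome` (a `proteome`) and `truth`
#'   (data frame: protein_id, family, is_paralog).
#' @export
generate_proteome <- function(family_specs = list(), n_singletons = 0,
                              genome_size = 2e6, seed,
                              organism_id = "ORG",
                              species_label = organism_id,
                              strain_label = "",
                              singleton_length = 300L) {
  for (fs in family_specs) {
    if (is.null(fs$identity) || fs$identity <= 0 || fs$identity > 1) {
      stop("target identity must be in (0, 1]")
    }
    if (is.null(fs$size) || fs$size < 1) stop("family size must be >= 1")
    if (is.null(fs$length) || fs$length < 30) {
      stop("protein length must be >= 30")
    }
  }
  with_seed(seed, {
    seqs <- character(0)
    cog <- list()
    truth <- list()
    for (fi in seq_along(family_specs)) {
      fs <- family_specs[[fi]]
      len <- as.integer(fs$length)
      s <- identity_to_subst_rate(fs$identity)
      ancestor <- sample(AA20, len, replace = TRUE)
      for (mi in seq_len(fs$size)) {
        member <- ancestor
        mut <- which(stats::rbinom(len, 1L, s) == 1L)
        if (length(mut)) {
          for (pos in mut) {
            member[pos] <- sample(setdiff(AA20, ancestor[pos]), 1L)
          }
        }
        id <- sprintf("%s_F%02d_%d", organism_id, fi, mi)
        seqs[id] <- paste(member, collapse = "")
        cog[[id]] <- if (!is.null(fs$cog)) as.character(fs$cog) else character(0)
        truth[[length(truth) + 1L]] <-
          data.frame(protein_id = id, family = fi, is_paralog = fs$size >= 2,
                     stringsAsFactors = FALSE)
      }
    }
    for (si in seq_len(n_singletons)) {
      id <- sprintf("%s_S%03d", organism_id, si)
      seqs[id] <- paste(sample(AA20, singleton_length, replace = TRUE),
                        collapse = "")
      cog[[id]] <- character(0)
    }
    truth_df <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(protein_id = character(0), family = integer(0),
                 is_paralog = logical(0), stringsAsFactors = FALSE)
    }
    list(proteome = proteome(organism_id, seqs, genome_size,
                             species_label, strain_label, cog),
         truth = truth_df)
  })
}

#' Generate a random ontology DAG
#'
#' Terms are created in order and parents are drawn only from
#' earlier-created terms, so the result is acyclic by construction. Each
#' root seeds one namespace (cycling process/function/component); a
#' non-root term inherits the namespace of its first parent, and extra
#' parents are drawn from that namespace.
#'
#' @param n_terms Total number of terms (>= n_roots).
#' @param n_roots Number of root terms (>= 1).
#' @param mean_parents Mean number of parents for non-root terms (>= 1).
#' @param part_of_fraction Probability that an edge is `part_of` rather
#'   than `is_a`.
#' @param seed RNG seed.
#' @return An `onto_dag`.
#' @export
generate_go_dag <- function(n_terms, n_roots = 1, mean_parents = 1.2,
                            part_of_fraction = 0.2, seed) {
  stopifnot(n_terms >= n_roots, n_roots >= 1, mean_parents >= 1)
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    ns_pool <- c("process", "function", "component")
    ns <- character(n_terms)
    names(ns) <- ids
    ns[seq_len(n_roots)] <- ns_pool[(seq_len(n_roots) - 1L) %% 3L + 1L]
    edges <- list()
    for (i in seq.int(n_roots + 1L, length.out = n_terms - n_roots)) {
      first <- sample.int(i - 1L, 1L)
      ns[i] <- ns[first]
      same_ns <- which(ns[seq_len(i - 1L)] == ns[i])
      n_extra <- stats::rpois(1L, mean_parents - 1)
      extra <- if (n_extra > 0 && length(same_ns) > 1) {
        sample(setdiff(same_ns, first), min(n_extra, length(same_ns) - 1L))
      } else integer(0)
      for (p in c(first, extra)) {
        rel <- if (stats::runif(1) < part_of_fraction) "part_of" else "is_a"
        edges[[length(edges) + 1L]] <- c(ids[i], ids[p], rel)
      }
    }
    ed <- if (length(edges)) {
      m <- do.call(rbind, edges)
      data.frame(child = m[, 1], parent = m[, 2], relation = m[, 3],
                 stringsAsFactors = FALSE)
    } else NULL
    onto_dag(ids, ed, namespaces = ns)
  })
}

#' Generate direct annotations with planted paranome enrichment
#'
#' Background annotations are drawn independently per (protein, term) at
#' `base_rate`. For organisms listed in `planted`, the planted term is
#' additionally assigned to that organism's paralog proteins at
#' `min(1, base_rate * fold)`, so `fold = 1` plants no signal.
#'
#' @param proteomes List of `proteome` objects.
#' @param dag An `onto_dag` (terms drawn from it).
#' @param paranomes Named list organism ID -> character vector of paralog
#'   protein IDs (the planted truth from [generate_proteome()] or a called
#'   paranome).
#' @param planted Named list organism ID -> named numeric vector mapping
#'   term ID to fold (>= 1).
#' @param base_rate Background per-(protein, term) annotation probability.
#' @param seed RNG seed.
#' @param background_terms Candidate terms for background annotation
#'   (default: all DAG terms).
#' @return List with `direct` (organism -> protein -> direct term IDs) and
#'   `truth` (data frame organism, term, fold of planted signals).
#' @export
generate_annotations <- function(proteomes, dag, paranomes,
                                 planted = list(), base_rate = 0.05, seed,
                                 background_terms = dag$terms) {
  stopifnot(base_rate >= 0, base_rate <= 1)
  for (org in names(planted)) {
    if (any(planted[[org]] < 1)) stop("planted fold must be >= 1")
  }
  with_seed(seed, {
    direct <- list()
    truth <- list()
    for (pr in proteomes) {
      org <- pr$organism_id
      prot_ids <- names(pr$proteins)
      ann <- rep(list(character(0)), length(prot_ids))
      names(ann) <- prot_ids
      if (base_rate > 0 && length(background_terms)) {
        draw <- matrix(stats::rbinom(length(prot_ids) * length(background_terms),
                                     1L, base_rate) == 1L,
                       nrow = length(prot_ids))
        for (i in seq_along(prot_ids)) {
          ann[[i]] <- background_terms[draw[i, ]]
        }
      }
      for (term in names(planted[[org]])) {
        fold <- planted[[org]][[term]]
        p_hit <- min(1, base_rate * fold)
        para <- intersect(paranomes[[org]], prot_ids)
        hit <- para[stats::rbinom(length(para), 1L, p_hit) == 1L]
        for (pid in hit) ann[[pid]] <- union(ann[[pid]], term)
        truth[[length(truth) + 1L]] <-
          data.frame(organism = org, term = term, fold = fold,
                     stringsAsFactors = FALSE)
      }
      direct[[org]] <- lapply(ann, function(x) sort(unique(x)))
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(organism = character(0), term = character(0),
                 fold = numeric(0), stringsAsFactors = FALSE)
    list(direct = direct, truth = truth_df)
  })
}

#' Generate a binary species-by-term incidence matrix with planted biclusters
#'
#' Every cell is first drawn Bernoulli(`noise_p`); planted blocks are then
#' forced to 1, so `noise_p = 0` leaves exactly the planted blocks and
#' `noise_p = 1` gives an all-ones matrix.
#'
#' @param n_species,n_terms Matrix dimensions.
#' @param planted_biclusters List of blocks, each a list with integer (or
#'   name) vectors `rows` and `cols`.
#' @param noise_p Background 1-probability.
#' @param seed RNG seed.
#' @return List with `matrix` (binary, dimnames S../T..) and `truth`
#'   (the planted blocks, as row/column name sets).
#' @export
generate_incidence <- function(n_species, n_terms, planted_biclusters = list(),
                               noise_p = 0.05, seed) {
  stopifnot(noise_p >= 0, noise_p <= 1)
  with_seed(seed, {
    m <- matrix(stats::rbinom(n_species * n_terms, 1L, noise_p),
                nrow = n_species,
                dimnames = list(sprintf("S%02d", seq_len(n_species)),
                                sprintf("T%02d", seq_len(n_terms))))
    truth <- lapply(planted_biclusters, function(b) {
      rows <- if (is.character(b$rows)) b$rows else rownames(m)[b$rows]
      cols <- if (is.character(b$cols)) b$cols else colnames(m)[b$cols]
      m[rows, cols] <<- 1L
      list(rows = sort(rows), cols = sort(cols))
    })
    list(matrix = m, truth = truth)
  })
}

#' Simulate 16S-like sequences along a tree under Jukes-Cantor
#'
#' The root sequence is uniform over ACGT; each branch substitutes sites
#' independently with probability 3/4 (1 - exp(-4 b / 3)) for branch length
#' b in expected substitutions per site, choosing uniformly among the three
#' alternative bases. The true pairwise distance between leaves is the path
#' length in the tree.
#'
#' @param tree An `ape` phylo object or a Newick string.
#' @param seq_length Sequence length in bases.
#' @param seed RNG seed.
#' @return List with `sequences` (named character, one per leaf),
#'   `distances` (true path-length matrix between leaves) and `tree`.
#' @export
generate_16s_set <- function(tree, seq_length, seed) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), seq_length >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  with_seed(seed, {
    tree <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      p_sub <- 0.75 * (1 - exp(-4 * b / 3))
      child_seq <- seqs[[parent]]
      if (p_sub > 0) {
        mut <- which(stats::rbinom(seq_length, 1L, p_sub) == 1L)
        if (length(mut)) {
          # uniform among the three alternative bases
          shift <- sample.int(3L, length(mut), replace = TRUE)
          child_seq[mut] <- (child_seq[mut] - 1L + shift) %% 4L + 1L
        }
      }
      seqs[[child]] <- child_seq
    }
    bases <- c("A", "C", "G", "T")
    out <- vapply(seq_len(n_tip),
                  function(i) paste(bases[seqs[[i]]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    dmat <- ape::cophenetic.phylo(tree)
    list(sequences = out, distances = dmat[names(out), names(out)],
         tree = tree)
  })
}
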