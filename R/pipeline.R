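#' Pipeline configuration with study defaults
#'
#' All thresholds default to the values the analysis is designed around:
#' 75% identity for paralog calling, E-value 1e-5 with at most 1000 hits
#' per query, the 200 highest-duplication organisms, Bonferroni-corrected
#' alpha 0.01 with the >= 3-organism term filter, species-graph edges at
#' >= 10 shared terms covering >= 30% of the maximum possible overlap,
#' 2x2 minimum bicluster size, and the convergence screen at similarity
#' > 0.7 and distance > 0.1.
#'
#' @param ... Named overrides of any default.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(identity_threshold = 75, evalue_max = 1e-5, max_hits = 1000,
              top_n = 200, alpha = 0.01, min_organisms = 3,
              min_count = 10, min_relative = 0.30,
              min_rows = 2, min_cols = 2,
              sim_cut = 0.7, dist_cut = 0.1,
              background = "all_paralogs",
              exclude_species = character(0),
              ease = FALSE, dedup = TRUE,
              seed = 1L, out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$identity_threshold >= 0, cfg$identity_threshold <= 100,
            cfg$evalue_max > 0, cfg$max_hits >= 1, cfg$top_n >= 1,
            cfg$alpha > 0, cfg$alpha <= 1, cfg$min_organisms >= 1,
            cfg$min_count >= 0, cfg$min_relative >= 0,
            cfg$min_relative <= 1, cfg$min_rows >= 1, cfg$min_cols >= 1,
            cfg$sim_cut >= 0, cfg$sim_cut <= 1, cfg$dist_cut >= 0)
  cfg$background <- match.arg(cfg$background,
                              c("all_paralogs", "all_proteomes",
                                "individual_proteome"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis end to end
#'
#' Executes the stages in order: paralog calling, fraction ranking, the
#' paralog-count/genome-size trend, COG profiling, per-organism
#' overrepresentation analysis against the configured background, the
#' cross-organism term filter, the species similarity graph,
#' binarization, BiMax biclustering, the single-species strain filter,
#' co-occurrence counting, within-cluster semantic similarity,
#' alignment-free distances, and the convergence screen. A stage failure
#' halts with the stage name in the error.
#'
#' @param world Input bundle: a list with elements `proteomes` (list of
#'   `proteome`), `annotations` (organism -> protein -> direct term IDs),
#'   `dag` (an `onto_dag`), `sixteen_s` (organism -> DNA sequence),
#'   `strain_map` (organism -> species label), and optionally
#'   `singletons` (protein IDs of persistent singletons for the COG
#'   comparison). [demo_world()] builds a complete example.
#' @param config A [pipeline_config()].
#' @return A `result_bundle`: `provenance` plus one entry per stage.
#'   When `config$out_dir` is set, all stage tables are also written
#'   there deterministically (same config and seed give byte-identical
#'   files).
#' @export
run_all <- function(world, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("proteomes", "annotations", "dag", "sixteen_s", "strain_map")
  miss <- setdiff(need, names(world))
  if (length(miss)) stop("world is missing: ", paste(miss, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  orgs <- vapply(world$proteomes, `[[`, "", "organism_id")
  names(world$proteomes) <- orgs

  paranomes <- stage("paralogs", {
    lapply(world$proteomes, function(pr) {
      hits <- all_vs_all(pr, evalue_max = config$evalue_max,
                         max_hits = config$max_hits)
      call_paralogs(hits, pr, identity_threshold = config$identity_threshold)
    })
  })
  para_ids <- lapply(paranomes, `[[`, "paralog_ids")

  rank <- stage("rank", {
    paralog_fraction_rank(paranomes,
                          top_n = min(config$top_n, length(paranomes)))
  })

  trend <- stage("trend", {
    pts <- data.frame(
      organism_id = rank$organism_id,
      genome_mb = vapply(rank$organism_id, function(o)
        world$proteomes[[o]]$genome_size / 1e6, 0),
      n_paralogs = rank$n_paralogs, stringsAsFactors = FALSE)
    if (nrow(pts) >= 3 && stats::sd(pts$genome_mb) > 0 &&
        stats::sd(pts$n_paralogs) > 0) {
      fit_trend(pts)
    } else NULL
  })

  cog_map <- do.call(c, unname(lapply(world$proteomes, `[[`, "cog")))
  all_protein_ids <- unlist(lapply(world$proteomes, function(p)
    names(p$proteins)), use.names = FALSE)
  cog <- stage("cog_profile", {
    paralog_dist <- cog_distribution(unlist(para_ids, use.names = FALSE),
                                     cog_map)
    singleton_ids <- if (!is.null(world$singletons)) world$singletons else
      setdiff(all_protein_ids, unlist(para_ids, use.names = FALSE))
    singleton_dist <- cog_distribution(singleton_ids, cog_map)
    reference_dist <- cog_distribution(all_protein_ids, cog_map)
    list(paralogs = paralog_dist, singletons = singleton_dist,
         reference = reference_dist,
         comparison = compare_distributions(paralog_dist, singleton_dist,
                                            reference_dist))
  })

  ann <- stage("propagate", {
    flat <- do.call(c, unname(world$annotations))
    propagate(flat, world$dag)
  })

  enrichment <- stage("enrichment", {
    keep <- rank$organism_id
    res <- lapply(keep, function(o) {
      bg <- background_model(config$background, world$proteomes,
                             para_ids, organism_id = o)
      enrich_organism(paranomes[[o]], bg, ann$propagated,
                      alpha = config$alpha, organism_id = o,
                      ease = config$ease)
    })
    do.call(rbind, res)
  })

  filtered <- stage("cross_organism_filter", {
    cross_organism_filter(enrichment, min_organisms = config$min_organisms)
  })

  graph <- stage("species_graph", {
    lists <- split(enrichment$term, enrichment$organism)
    for (o in setdiff(rank$organism_id, names(lists))) {
      lists[[o]] <- character(0)
    }
    if (length(lists) >= 2) {
      g <- build_graph(lists, min_count = config$min_count,
                       min_relative = config$min_relative)
      list(graph = g, summary = graph_summary(g))
    } else NULL
  })

  bic <- stage("biclustering", {
    if (!nrow(filtered)) {
      list(matrix = NULL, unclusterable = character(0), biclusters = list(),
           removed_by_species = integer(0))
    } else {
      bz <- binarize(filtered)
      clusters <- if (nrow(bz$matrix) >= config$min_rows &&
                      ncol(bz$matrix) >= config$min_cols) {
        bimax(bz$matrix, min_rows = config$min_rows,
              min_cols = config$min_cols)
      } else list()
      filt <- drop_single_species_clusters(clusters, world$strain_map)
      c(bz, filt)
    }
  })

  cooc <- stage("cooccurrence", {
    cooccurrence_counts(bic$biclusters, world$strain_map,
                        exclude_species = config$exclude_species)
  })

  dmat <- stage("krdist", {
    seqs <- world$sixteen_s
    distance_matrix(seqs[names(seqs) %in% rank$organism_id])
  })

  scores <- stage("cluster_scores", {
    bcs <- bic$biclusters
    if (!length(bcs)) {
      data.frame(cluster_id = integer(0), go_similarity = numeric(0),
                 phylo_distance = numeric(0), consensus_cog = character(0),
                 cog_support = numeric(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(bcs), function(i) {
        b <- bcs[[i]]
        members <- unlist(lapply(b$rows, function(o) {
          p <- para_ids[[o]]
          p[vapply(p, function(pid)
            any(b$cols %in% ann$propagated[[pid]]), logical(1))]
        }), use.names = FALSE)
        cc <- if (length(members)) consensus_cog(members, cog_map) else
          list(category = "-", support = 1)
        data.frame(cluster_id = i,
                   go_similarity = as.numeric(
                     cluster_similarity(b$cols, world$dag)),
                   phylo_distance = cluster_distance(b, dmat),
                   consensus_cog = cc$category,
                   cog_support = cc$support,
                   stringsAsFactors = FALSE)
      }))
    }
  })

  calls <- stage("convergence", {
    if (!nrow(scores)) {
      data.frame(cluster_id = integer(0), go_similarity = numeric(0),
                 phylo_distance = numeric(0), n_organisms = integer(0),
                 n_terms = integer(0), selected = logical(0))
    } else {
      select_convergent(scores, bic$biclusters, sim_cut = config$sim_cut,
                        dist_cut = config$dist_cut, dedup = config$dedup)
    }
  })

  bundle <- structure(list(
    provenance = list(
      config = unclass(config)[setdiff(names(config), "out_dir")],
      n_organisms = length(world$proteomes),
      n_terms = length(world$dag$terms)
    ),
    paranomes = paranomes, rank = rank, trend = trend, cog = cog,
    annotations = ann, enrichment = enrichment, filtered = filtered,
    species_graph = graph, biclustering = bic, cooccurrence = cooc,
    distance_matrix = dmat, cluster_scores = scores,
    convergence_calls = calls
  ), class = "result_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @noRd
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(bundle$rank, p("paralog_rank.tsv"))
  if (!is.null(bundle$trend)) {
    tr <- bundle$trend
    write_tsv(data.frame(slope = tr$slope, intercept = tr$intercept,
                         pearson_r = tr$pearson_r,
                         outliers = paste(tr$outlier_ids, collapse = ",")),
              p("trend_fit.tsv"))
  }
  write_tsv(bundle$cog$comparison, p("cog_comparison.tsv"))
  write_tsv(bundle$enrichment, p("enrichment.tsv"))
  write_tsv(bundle$filtered, p("enrichment_filtered.tsv"))
  if (!is.null(bundle$species_graph)) {
    write_edge_list(bundle$species_graph$graph, p("species_graph.tsv"))
  }
  if (!is.null(bundle$biclustering$matrix)) {
    write_matrix(bundle$biclustering$matrix, p("incidence.tsv"))
  }
  jsonlite::write_json(bundle$biclustering$biclusters, p("biclusters.json"),
                       pretty = TRUE)
  write_tsv(bundle$cooccurrence, p("cooccurrence.tsv"))
  write_matrix(bundle$distance_matrix, p("distance_matrix.tsv"))
  write_phylip(bundle$distance_matrix, p("distance_matrix.phy"))
  write_tsv(bundle$cluster_scores, p("cluster_scores.tsv"))
  write_tsv(bundle$convergence_calls, p("convergence_calls.tsv"))
  jsonlite::write_json(bundle$provenance, p("provenance.json"),
                       pretty = TRUE, auto_unbox = TRUE)
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' @param bundle A `result_bundle` from [run_all()].
#' @return Invisibly, the report lines; also printed.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("== paralog / duplication analysis ==")
  add(sprintf("organisms: %d; ranked: %d", bundle$provenance$n_organisms,
              nrow(bundle$rank)))
  top <- bundle$rank[1, ]
  add(sprintf("highest paralog fraction: %s (%.2f%%)", top$organism_id,
              100 * top$paralog_fraction))
  if (!is.null(bundle$trend)) {
    add(sprintf("paralogs ~ genome size: y = %.2fx + %.2f (r = %.3f)",
                bundle$trend$slope, bundle$trend$intercept,
                bundle$trend$pearson_r))
  }
  add("")
  add("== COG category comparison (paralogs vs singletons) ==")
  cmp <- bundle$cog$comparison
  flagged <- cmp[cmp$flag != "", , drop = FALSE]
  if (nrow(flagged)) {
    for (i in seq_len(nrow(flagged))) {
      add(sprintf("  %s: %s (paralog %.3f vs singleton %.3f)",
                  flagged$category[i], flagged$flag[i],
                  flagged$paralog_fraction[i], flagged$singleton_fraction[i]))
    }
  } else add("  no dominated categories")
  add("")
  add("== overrepresentation ==")
  add(sprintf("enriched records: %d; after >=%d-organism filter: %d",
              nrow(bundle$enrichment),
              bundle$provenance$config$min_organisms, nrow(bundle$filtered)))
  if (!is.null(bundle$species_graph)) {
    s <- bundle$species_graph$summary
    add(sprintf("species graph: %d nodes, %d edges, %d component(s)",
                s$n_nodes, s$n_edges, s$n_components))
  }
  add("")
  add("== biclustering ==")
  add(sprintf("biclusters: %d (after strain filter); unclusterable organisms: %d",
              length(bundle$biclustering$biclusters),
              length(bundle$biclustering$unclusterable)))
  add("")
  add("== convergence screen ==")
  sel <- bundle$convergence_calls[bundle$convergence_calls$selected, ,
                                  drop = FALSE]
  if (!nrow(sel)) {
    add("zero convergent clusters selected")
  } else {
    add(sprintf("%d convergent cluster(s) selected (similarity > %.2f, distance > %.2f):",
                nrow(sel), bundle$provenance$config$sim_cut,
                bundle$provenance$config$dist_cut))
    for (i in seq_len(nrow(sel))) {
      b <- bundle$biclustering$biclusters[[sel$cluster_id[i]]]
      sc <- bundle$cluster_scores[
        bundle$cluster_scores$cluster_id == sel$cluster_id[i], ]
      add(sprintf("  cluster %d [COG %s]: similarity %.3f, distance %.3f",
                  sel$cluster_id[i], sc$consensus_cog, sel$go_similarity[i],
                  sel$phylo_distance[i]))
      add("    organisms: ", paste(b$rows, collapse = ", "))
      add("    terms: ", paste(b$cols, collapse = ", "))
    }
  }
  add("")
  add("== provenance ==")
  cfg <- bundle$provenance$config
  for (k in sort(names(cfg))) {
    add(sprintf("  %s = %s", k, paste(cfg[[k]], collapse = ",")))
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("result bundle:", nrow(x$rank), "organisms,",
      length(x$biclustering$biclusters), "biclusters,",
      sum(x$convergence_calls$selected), "convergent cluster(s)\n")
  invisible(x)
}
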