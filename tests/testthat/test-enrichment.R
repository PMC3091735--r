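test_that("the Fisher tail matches the exhaustive summation oracle", {
  expect_equal(fisher_p(4, 5, 10, 100), fisher_oracle(4, 5, 10, 100),
               tolerance = 1e-14)
  expect_identical(fisher_p(0, 5, 10, 100), 1)
  expect_identical(fisher_p(7, 7, 7, 7), 1)
  set.seed(202)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    n <- sample(0:N, 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisher_p(k, n, K, N), fisher_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("the Fisher tail is monotone in k and validates its bounds", {
  p <- fisher_p(0:8, 10, 8, 40)
  expect_true(all(diff(p) <= 0))
  expect_error(fisher_p(6, 5, 10, 100), "k must be <= n")
  expect_error(fisher_p(2, 5, 10, 8), "K must be <= N")
  expect_error(fisher_p(3, 5, 2, 100), "k must be <= K")
})

test_that("the EASE variant is never less conservative than classical Fisher", {
  set.seed(203)
  for (i in 1:50) {
    N <- sample(20:80, 1); n <- sample(5:N, 1)
    K <- sample(5:N, 1); k <- sample(1:min(n, K), 1)
    expect_gte(fisher_p(k, n, K, N, ease = TRUE), fisher_p(k, n, K, N))
  }
})

enrich_fixture <- function(seed, fold, base_rate = 0.04) {
  dag <- generate_go_dag(40, seed = 900)
  prs <- lapply(sprintf("G%02d", 1:5), dummy_proteome, n_proteins = 500)
  paranomes <- stats::setNames(lapply(prs, function(p)
    names(p$proteins)[1:30]), sprintf("G%02d", 1:5))
  planted <- list(G01 = c(T0030 = fold))
  ann <- generate_annotations(prs, dag, paranomes, planted = planted,
                              base_rate = base_rate, seed = seed)
  bg_ids <- sort(unlist(paranomes, use.names = FALSE))
  prop <- propagate(do.call(c, unname(ann$direct))[bg_ids], dag)
  list(study = paranomes$G01, bg = bg_ids, annotations = prop$propagated)
}

test_that("a fold-20 planted term is detected against the paralog background", {
  fx <- enrich_fixture(seed = 1234, fold = 20)
  res <- enrich_organism(fx$study, fx$bg, fx$annotations, alpha = 0.01,
                         organism_id = "G01")
  expect_true("T0030" %in% res$term)
  rec <- res[res$term == "T0030", ]
  expect_identical(rec$n, 30L)
  expect_identical(rec$N, 150L)
  expect_lte(rec$k, min(rec$n, rec$K))
  expect_equal(rec$p_bonferroni, pmin(1, rec$p_raw * rec$m))
})

test_that("testing the study set against itself finds nothing", {
  fx <- enrich_fixture(seed = 77, fold = 20)
  res <- enrich_organism(fx$study, fx$study, fx$annotations, alpha = 0.01)
  expect_identical(nrow(res), 0L)
})

test_that("Bonferroni arithmetic and the alpha cutoff are applied as stated", {
  # m tests at p_raw = 1e-4 gives p_bonferroni = m * 1e-4
  ann <- c(lapply(1:4, function(i) "T1"), lapply(1:16, function(i)
    character(0)))
  names(ann) <- paste0("p", 1:20)
  res <- enrich_organism(paste0("p", 1:5), paste0("p", 1:20), ann,
                         alpha = 1.1)
  expect_identical(res$m, 1L)
  expect_equal(res$p_bonferroni, res$p_raw)
  expect_warning(out <- enrich_organism(character(0), paste0("p", 1:20),
                                        ann), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("the cross-organism filter keeps terms in >= min organisms", {
  rec <- function(org, term) data.frame(organism = org, term = term,
                                        k = 5L, n = 10L, K = 10L, N = 100L,
                                        m = 3L, p_raw = 1e-5,
                                        p_bonferroni = 3e-5,
                                        stringsAsFactors = FALSE)
  df <- rbind(rec("A", "t1"), rec("B", "t1"), rec("A", "t2"), rec("B", "t2"),
              rec("C", "t2"))
  out <- cross_organism_filter(df, min_organisms = 3)
  expect_identical(unique(out$term), "t2")
  expect_identical(nrow(out), 3L)
  out1 <- cross_organism_filter(df, min_organisms = 1)
  expect_identical(out1, df)
})

test_that("background models have the documented membership relations", {
  prs <- list(dummy_proteome("A", 10), dummy_proteome("B", 10))
  paranomes <- list(A = sprintf("A_p%03d", 1:3), B = sprintf("B_p%03d", 1:2))
  all_par <- background_model("all_paralogs", prs, paranomes)
  all_pro <- background_model("all_proteomes", prs, paranomes)
  ind <- background_model("individual_proteome", prs, paranomes,
                          organism_id = "A")
  expect_length(all_par$members, 5L)
  expect_length(all_pro$members, 20L)
  expect_length(ind$members, 10L)
  expect_true(all(paranomes$A %in% all_par$members))
  expect_true(all(all_par$members %in% all_pro$members))
  expect_true(all(paranomes$A %in% ind$members))
  # all three run to internally valid records on the same fixture
  ann <- stats::setNames(rep(list("T1"), 20),
                         c(sprintf("A_p%03d", 1:10), sprintf("B_p%03d", 1:10)))
  for (bg in list(all_par, all_pro, ind)) {
    res <- enrich_organism(paranomes$A, bg, ann, alpha = 1.1,
                           organism_id = "A")
    expect_true(all(res$k <= pmin(res$n, res$K)))
    expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  }
})
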