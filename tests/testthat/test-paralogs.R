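test_that("identical proteins produce reciprocal hits at 100% identity", {
  s <- random_protein(300)
  pr <- proteome("org", c(p1 = s, p2 = s), 1e6)
  hits <- all_vs_all(pr)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$qseqid, c("p1", "p2"))
  expect_true(all(hits$pident == 100))
})

test_that("unrelated random proteins never reach the E-value cutoff", {
  set.seed(33)
  for (i in 1:20) {
    pr <- proteome("org", c(a = random_protein(300), b = random_protein(300)),
                   1e6)
    expect_identical(nrow(all_vs_all(pr)), 0L)
  }
})

test_that("a planted family's reported identity tracks the planted value", {
  gp <- generate_proteome(list(list(size = 2, identity = 0.8, length = 300)),
                          seed = 44)
  hits <- all_vs_all(gp$proteome)
  expect_gte(nrow(hits), 2L)
  # local alignment may trim the worst flanks, so the reported identity
  # sits at or slightly above the site-wise (ungapped) oracle
  sp <- strsplit(gp$proteome$proteins, "")
  positional <- 100 * mean(sp[[1]] == sp[[2]])
  expect_true(all(hits$pident >= positional - 0.5))
  expect_true(all(abs(hits$pident - 80) <= 5))
})

test_that("hits are symmetric in identity up to local-alignment tolerance", {
  gp <- generate_proteome(list(list(size = 3, identity = 0.85, length = 200),
                               list(size = 2, identity = 0.9, length = 150)),
                          n_singletons = 4, seed = 55)
  hits <- all_vs_all(gp$proteome)
  key <- paste(pmin(hits$qseqid, hits$sseqid), pmax(hits$qseqid, hits$sseqid))
  for (k in unique(key)) {
    pid <- hits$pident[key == k]
    expect_lte(max(pid) - min(pid), 1)
  }
})

test_that("illegal residues abort with the protein named", {
  pr <- proteome("org", c(ok = "MKVLY"), 1e6)
  pr$proteins[["ok"]] <- "MKB1"
  expect_error(all_vs_all(pr), "ok")
})

test_that("paralog calling counts proteins once and respects the threshold", {
  pr <- proteome("org", stats::setNames(replicate(10, random_protein(100)),
                                        paste0("p", 1:10)), 1e6)
  hits <- data.frame(qseqid = c("p1", "p2"), sseqid = c("p2", "p1"),
                     pident = c(80, 80), length = 100, evalue = 1e-30,
                     stringsAsFactors = FALSE)
  pn <- call_paralogs(hits, pr)
  expect_identical(pn$paralog_ids, c("p1", "p2"))
  expect_identical(pn$paralog_fraction, 0.2)
  none <- call_paralogs(hits[0, ], pr)
  expect_identical(none$paralog_fraction, 0)
  expect_length(none$paralog_ids, 0L)
})

test_that("raising the identity threshold never grows the paralog set", {
  for (seed in c(61, 62)) {
    gp <- generate_proteome(list(list(size = 3, identity = 0.9, length = 150),
                                 list(size = 2, identity = 0.8, length = 150)),
                            n_singletons = 5, seed = seed)
    hits <- all_vs_all(gp$proteome)
    prev <- NULL
    for (thr in c(60, 70, 75, 85, 95)) {
      ids <- call_paralogs(hits, gp$proteome, thr)$paralog_ids
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("planted truth is recovered exactly at the default threshold", {
  gp <- generate_proteome(list(list(size = 3, identity = 0.9, length = 150)),
                          n_singletons = 17, seed = 77)
  pn <- call_paralogs(all_vs_all(gp$proteome), gp$proteome)
  expect_setequal(pn$paralog_ids, gp$truth$protein_id[gp$truth$is_paralog])
  expect_identical(pn$paralog_fraction, 0.15)
})

test_that("ranking is descending with lexicographic, flagged ties", {
  mk <- function(org, ids, n) structure(
    list(organism_id = org, paralog_ids = ids,
         paralog_fraction = length(ids) / n, n_proteins = n),
    class = "paranome")
  rk <- paralog_fraction_rank(list(mk("A", "x", 10), mk("B", c("x", "y", "z"),
                                                        10)), top_n = 1)
  expect_identical(rk$organism_id, "B")
  rk2 <- paralog_fraction_rank(list(mk("B", c("a", "b"), 10),
                                    mk("A", c("c", "d"), 10)), top_n = 2)
  expect_identical(rk2$organism_id, c("A", "B"))
  expect_true(all(rk2$tied))
  expect_warning(paralog_fraction_rank(list(mk("A", "x", 10)), top_n = 5),
                 "exceeds")
})

test_that("trend fitting recovers exact and noisy linear relations", {
  pts <- data.frame(genome_mb = 1:10, n_paralogs = 27 * (1:10) + 13)
  fit <- fit_trend(pts)
  expect_equal(fit$slope, 27, tolerance = 1e-10)
  expect_equal(fit$intercept, 13, tolerance = 1e-8)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_length(fit$outlier_ids, 0L)

  set.seed(88)
  x <- runif(100, 1, 8)
  noisy <- data.frame(genome_mb = x, n_paralogs = 25 * x + 10 + rnorm(100, 0, 5))
  fit2 <- fit_trend(noisy)
  expect_lt(abs(fit2$slope - 25), 2)

  expect_error(fit_trend(data.frame(genome_mb = rep(2, 5),
                                    n_paralogs = 1:5)), "variance")
})

test_that("gross outliers are flagged and the refit improves correlation", {
  set.seed(99)
  x <- seq(1, 8, length.out = 40)
  y <- 20 * x + 5 + rnorm(40, 0, 3)
  y[40] <- y[40] + 400
  pts <- data.frame(organism_id = paste0("o", 1:40), genome_mb = x,
                    n_paralogs = y)
  fit <- fit_trend(pts)
  expect_identical(fit$outlier_ids, "o40")
  expect_gt(fit$fit_excluding$pearson_r, fit$pearson_r)
})
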