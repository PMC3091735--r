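test_that("the substring profile equals the naive search oracle", {
  set.seed(808)
  q <- random_dna(300)
  s <- random_dna(400)
  expect_identical(as.integer(shulen_profile(q, s)),
                   naive_match_stat(q, s) + 1L)
  # related pair: mutate a copy so long shared stretches exist
  s2 <- strsplit(q, "")[[1]]
  mut <- sample(300, 15)
  s2[mut] <- sample(c("A", "C", "G", "T"), 15, replace = TRUE)
  s2 <- paste(s2, collapse = "")
  expect_identical(as.integer(shulen_profile(q, s2)),
                   naive_match_stat(q, s2) + 1L)
})

test_that("self-comparison follows the remaining-length + 1 convention", {
  q <- random_dna(200)
  prof <- shulen_profile(q, q)
  expect_identical(as.integer(prof), rev(seq_len(200)) + 1L)
})

test_that("a single mismatch dips the profile around its position", {
  set.seed(809)
  q <- random_dna(1000)
  s <- strsplit(q, "")[[1]]
  s[500] <- setdiff(c("A", "C", "G", "T"), s[500])[1]
  s <- paste(s, collapse = "")
  prof <- shulen_profile(q, s)
  expect_identical(as.integer(prof), naive_match_stat(q, s) + 1L)
  expect_lt(min(prof[480:500]), min(prof[c(1:400)]))
})

test_that("profile inputs are validated and cleaned", {
  expect_error(shulen_profile(random_dna(50), random_dna(500)), "100")
  expect_warning(shulen_profile(paste0(random_dna(150), "NNN"),
                                random_dna(200)), "stripped")
})

test_that("identical sequences give exactly zero distance", {
  q <- random_dna(2000)
  d <- kr_distance(q, q)
  expect_identical(as.numeric(d), 0)
  expect_false(attr(d, "saturated"))
})

test_that("a simulated JC pair at d = 0.1 is estimated within 0.02", {
  sim <- generate_16s_set("(L1:0.05,L2:0.05);", 50000, seed = 42)
  d <- kr_distance(sim$sequences[["L1"]], sim$sequences[["L2"]])
  expect_gte(as.numeric(d), 0.08)
  expect_lte(as.numeric(d), 0.12)
  expect_false(attr(d, "saturated"))
  # agrees with the alignment-based JC oracle
  oracle <- jc_oracle(sim$sequences[["L1"]], sim$sequences[["L2"]])
  expect_lt(abs(as.numeric(d) - oracle), 0.02)
})

test_that("independent random sequences are flagged saturated and capped", {
  set.seed(810)
  for (i in 1:10) {
    d <- kr_distance(random_dna(2000), random_dna(2000))
    expect_true(attr(d, "saturated"))
    expect_true(is.finite(as.numeric(d)))
  }
})

test_that("short sequences warn about wide uncertainty", {
  set.seed(811)
  expect_warning(kr_distance(random_dna(500), random_dna(500)), "1 kb")
})

test_that("distance matrices are symmetric with zero diagonal", {
  q <- random_dna(2000)
  dm <- distance_matrix(c(a = q, b = q, c = q))
  expect_true(all(dm == 0))
  expect_warning(dm2 <- distance_matrix(list(a = q, b = q, miss = NA)),
                 "dropped")
  expect_identical(rownames(dm2), c("a", "b"))

  sim <- generate_16s_set("(x:0.05,y:0.05,z:0.05);", 20000, seed = 13)
  dm3 <- distance_matrix(sim$sequences)
  expect_identical(dm3, t(dm3))
  expect_true(all(diag(dm3) == 0))
  off <- dm3[upper.tri(dm3)]
  expect_true(all(off > 0.07 & off < 0.13))
})

test_that("cluster distance averages pairs and checks membership", {
  dm <- matrix(c(0, 0.1, 0.2,
                 0.1, 0, 0.4,
                 0.2, 0.4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_identical(cluster_distance(c("a", "b"), dm), 0.1)
  expect_equal(cluster_distance(c("a", "b", "c"), dm), mean(c(0.1, 0.2, 0.4)))
  expect_identical(cluster_distance(list(rows = c("a", "b", "c")), dm,
                                    method = "max"), 0.4)
  expect_identical(cluster_distance("a", dm), 0)
  expect_error(cluster_distance(c("a", "zz"), dm), "zz")
})

test_that("the convergence screen applies strict cuts and size-first dedup", {
  bcs <- list(`1` = list(rows = c("a", "b", "c", "d", "e"),
                         cols = c("t1", "t2")),
              `2` = list(rows = c("a", "b", "c"), cols = c("t1", "t3")),
              `3` = list(rows = c("x", "y"), cols = c("t4", "t5")))
  scores <- data.frame(cluster_id = c("1", "2", "3"),
                       go_similarity = c(0.8, 0.75, 0.8),
                       phylo_distance = c(0.15, 0.15, 0.05),
                       stringsAsFactors = FALSE)
  out <- select_convergent(scores, bcs)
  expect_false(out$selected[out$cluster_id == "3"])  # distance too small
  # overlapping pair: the 3-organism cluster wins over the 5-organism one
  expect_true(out$selected[out$cluster_id == "2"])
  expect_false(out$selected[out$cluster_id == "1"])

  edge <- data.frame(cluster_id = "2", go_similarity = 0.8,
                     phylo_distance = 0.05, stringsAsFactors = FALSE)
  expect_false(any(select_convergent(edge, bcs)$selected))
  at_cut <- data.frame(cluster_id = "2", go_similarity = 0.7,
                       phylo_distance = 0.2, stringsAsFactors = FALSE)
  expect_false(any(select_convergent(at_cut, bcs)$selected))  # strict >
})
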