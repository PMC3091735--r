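test_that("binarization excludes organisms with fewer than two terms", {
  df <- data.frame(organism = c("A", "A", "B", "B", "C"),
                   term = c("t1", "t2", "t1", "t2", "t1"),
                   stringsAsFactors = FALSE)
  bz <- binarize(df)
  expect_identical(dim(bz$matrix), c(2L, 2L))
  expect_true(all(bz$matrix == 1L))
  expect_identical(bz$unclusterable, "C")
  expect_error(binarize(df[0, ]), "no enrichment")
})

test_that("degenerate matrices give the expected bicluster sets", {
  ones <- matrix(1L, 3, 3, dimnames = list(paste0("r", 1:3),
                                           paste0("c", 1:3)))
  res <- bimax(ones)
  expect_length(res, 1L)
  expect_identical(res[[1]]$rows, paste0("r", 1:3))
  expect_identical(res[[1]]$cols, paste0("c", 1:3))

  eye <- diag(3)
  dimnames(eye) <- dimnames(ones)
  expect_length(bimax(eye), 0L)
})

test_that("enumeration equals the brute-force oracle on random matrices", {
  set.seed(606)
  for (i in 1:40) {
    nr <- sample(4:8, 1)
    nc <- sample(4:8, 1)
    m <- matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.8)), nr,
                dimnames = list(sprintf("r%02d", 1:nr),
                                sprintf("c%02d", 1:nc)))
    expect_identical(canonical_biclusters(bimax(m)),
                     canonical_biclusters(brute_force_biclusters(m)))
  }
})

test_that("every reported bicluster is all-ones and inclusion-maximal", {
  set.seed(607)
  m <- matrix(rbinom(80, 1, 0.5), 8,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:10)))
  for (b in bimax(m)) {
    sub <- m[b$rows, b$cols, drop = FALSE]
    expect_true(all(sub == 1L))
    extra_rows <- setdiff(rownames(m), b$rows)
    if (length(extra_rows)) {
      expect_false(any(rowSums(m[extra_rows, b$cols, drop = FALSE]) ==
                         length(b$cols)))
    }
    extra_cols <- setdiff(colnames(m), b$cols)
    if (length(extra_cols)) {
      expect_false(any(colSums(m[b$rows, extra_cols, drop = FALSE]) ==
                         length(b$rows)))
    }
  }
})

test_that("planted blocks survive low noise inside some reported bicluster", {
  for (seed in c(11, 12, 13)) {
    gi <- generate_incidence(10, 10,
                             list(list(rows = 2:5, cols = 3:6)),
                             noise_p = 0.05, seed = seed)
    res <- bimax(gi$matrix)
    planted <- gi$truth[[1]]
    contained <- any(vapply(res, function(b) {
      all(planted$rows %in% b$rows) && all(planted$cols %in% b$cols)
    }, logical(1)))
    expect_true(contained)
  }
})

test_that("the enumeration budget guard triggers on pathological input", {
  m <- 1L - diag(12L)
  dimnames(m) <- list(paste0("r", 1:12), paste0("c", 1:12))
  expect_error(bimax(m, max_biclusters = 10), "budget")
})

test_that("single-species strain clusters are removed with a report", {
  strain_map <- c(e1 = "E. coli", e2 = "E. coli", e3 = "E. coli",
                  s1 = "S. aureus", b1 = "B. subtilis")
  bcs <- list(list(rows = c("e1", "e2", "e3"), cols = c("t1", "t2")),
              list(rows = c("s1", "b1"), cols = c("t1", "t2")))
  out <- drop_single_species_clusters(bcs, strain_map)
  expect_length(out$biclusters, 1L)
  expect_identical(out$biclusters[[1]]$rows, c("s1", "b1"))
  expect_identical(out$removed_by_species[["E. coli"]], 1L)

  expect_warning(
    drop_single_species_clusters(list(list(rows = c("e1", "zz"),
                                           cols = "t1")), strain_map),
    "zz")
})

test_that("co-occurrence counts match planted block membership at zero noise", {
  gi <- generate_incidence(8, 8,
                           list(list(rows = 1:3, cols = 1:4),
                                list(rows = 3:5, cols = 4:6)),
                           noise_p = 0, seed = 3)
  res <- bimax(gi$matrix)
  cc <- cooccurrence_counts(res)
  # S03/T04 sits in both planted blocks
  both <- cc[cc$organism == "S03" & cc$term == "T04", "count"]
  expect_identical(both, 2L)
  one <- cc[cc$organism == "S01" & cc$term == "T01", "count"]
  expect_identical(one, 1L)

  strain_map <- stats::setNames(c("sp1", rep("spX", 7)),
                                sprintf("S%02d", 1:8))
  cc2 <- cooccurrence_counts(res, strain_map, exclude_species = "sp1")
  expect_false("S01" %in% cc2$organism)
  expect_true("S02" %in% cc2$organism)
})
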