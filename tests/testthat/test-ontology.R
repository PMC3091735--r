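test_that("OBO parsing keeps is_a/part_of, resolves alt_ids, drops obsolete", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child",
    "namespace: biological_process", "alt_id: GO:0000099",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: part",
    "namespace: biological_process",
    "relationship: part_of GO:0000002 ! child", "",
    "[Term]", "id: GO:0000004", "name: gone", "is_obsolete: true",
    "is_a: GO:0000001", "",
    "[Typedef]", "id: part_of", "name: part of"
  ), f)
  dag <- read_obo(f)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_identical(dag$edges$relation, c("is_a", "part_of"))
  expect_identical(dag_resolve(dag, "GO:0000099"), "GO:0000002")
  expect_true(is.na(dag_resolve(dag, "GO:0000004")))
  expect_identical(dag$namespaces[["GO:0000003"]], "process")
})

test_that("a cyclic ontology is rejected with an explicit cycle", {
  ed <- data.frame(child = c("a", "b", "c"), parent = c("b", "c", "a"),
                   relation = "is_a", stringsAsFactors = FALSE)
  expect_error(onto_dag(c("a", "b", "c"), ed), "cycle")
})

test_that("edges referencing obsolete terms are dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "name: a", "",
    "[Term]", "id: B", "name: b", "is_obsolete: true", "",
    "[Term]", "id: C", "name: c", "is_a: B", "is_a: A"
  ), f)
  expect_warning(dag <- read_obo(f), "obsolete")
  expect_identical(dag$edges$parent, "A")
})

test_that("ancestors traverse chains and diamonds correctly", {
  dag <- chain_dag()
  expect_identical(dag_ancestors(dag, "c"), c("a", "b"))
  diamond <- onto_dag(c("top", "l", "r", "bot"),
                      data.frame(child = c("l", "r", "bot", "bot"),
                                 parent = c("top", "top", "l", "r"),
                                 relation = "is_a", stringsAsFactors = FALSE))
  expect_identical(dag_ancestors(diamond, "bot"), c("l", "r", "top"))
  expect_error(dag_ancestors(dag, "zzz"), "unknown")
})

test_that("propagation ancestor-closes annotations and drops unknown terms", {
  dag <- chain_dag()
  res <- propagate(list(p1 = "c", p2 = character(0)), dag)
  expect_identical(res$propagated$p1, c("a", "b", "c"))
  expect_identical(res$propagated$p2, character(0))
  expect_true(all(mapply(function(d, p) all(d %in% p),
                         res$direct, res$propagated)))

  diamond <- onto_dag(c("top", "l", "r", "bot"),
                      data.frame(child = c("l", "r", "bot", "bot"),
                                 parent = c("top", "top", "l", "r"),
                                 relation = "is_a", stringsAsFactors = FALSE))
  res2 <- propagate(list(p = "bot"), diamond)
  expect_identical(sum(res2$propagated$p == "top"), 1L)

  expect_warning(res3 <- propagate(list(p = c("c", "nope")), dag), "unknown")
  expect_identical(res3$propagated$p, c("a", "b", "c"))
})

test_that("propagation can be restricted to is_a edges", {
  dag <- onto_dag(c("a", "b", "c"),
                  data.frame(child = c("b", "c"), parent = c("a", "b"),
                             relation = c("is_a", "part_of"),
                             stringsAsFactors = FALSE))
  res <- propagate(list(p = "c"), dag, relations = "is_a")
  expect_identical(res$propagated$p, "c")  # the part_of link is not crossed
  res2 <- propagate(list(p = "b"), dag, relations = "is_a")
  expect_identical(res2$propagated$p, c("a", "b"))
})

test_that("generated DAGs are always acyclic and forests when asked", {
  for (seed in 1:10) {
    dag <- generate_go_dag(40, n_roots = 2, mean_parents = 1.6,
                           part_of_fraction = 0.3, seed = seed)
    expect_length(dag_topo_order(dag), 40L)
  }
  single <- generate_go_dag(1, seed = 5)
  expect_identical(nrow(single$edges), 0L)
  forest <- generate_go_dag(30, n_roots = 3, mean_parents = 1,
                            part_of_fraction = 0, seed = 9)
  expect_true(all(table(forest$edges$child) == 1))
  expect_true(all(forest$edges$relation == "is_a"))
})
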