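test_that("OBO parsing keeps is_a/part_of, drops obsolete terms and other relations", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: a",
    "namespace: molecular_function", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: b",
    "namespace: molecular_function",
    "relationship: part_of GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: molecular_function", "is_a: GO:0000001",
    "is_obsolete: true", "",
    "[Term]", "id: GO:0000005", "name: reg",
    "namespace: molecular_function",
    "relationship: regulates GO:0000001", ""
  ), obo)
  expect_warning(dags <- load_obo(obo), "dropped")
  dag <- dags$MF
  expect_false("GO:0000004" %in% dag$terms)       # obsolete excluded
  expect_setequal(dag$terms,
                  c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000005"))
  expect_equal(nrow(dag$edges), 2)                 # regulates edge dropped
  expect_setequal(dag$edges$relation, c("is_a", "part_of"))
})

test_that("missing files and cyclic graphs are fatal", {
  expect_error(load_obo(tempfile()), "not found")
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    relation = "is_a")
  expect_error(ontology_dag(cyc, "MF"), "cycl")
})

test_that("S-values follow the max-product recursion with the printed edge weights", {
  # direct is_a parent: contribution decays by 0.8
  a <- term_ancestry(two_node_dag("is_a"), "A")
  expect_identical(a$s_value[["A"]], 1)
  expect_equal(a$s_value[["R"]], 0.8)
  expect_equal(a$sv_total, 1.8)
  # two-step chain: 0.8 * 0.8
  chain <- ontology_dag(data.frame(child = c("M", "A"), parent = c("R", "M"),
                                   relation = "is_a"), "BP")
  expect_equal(term_ancestry(chain, "A")$s_value[["R"]], 0.64)
  # part_of decays by 0.6
  p <- term_ancestry(two_node_dag("part_of"), "A")
  expect_equal(p$s_value[["R"]], 0.6)
  expect_equal(p$sv_total, 1.6)
  expect_error(term_ancestry(two_node_dag(), "Z"), "Z")
})

test_that("multi-parent terms take the best child path", {
  # A -> {B, C} -> R with one part_of route; R's S-value is the max route
  edges <- data.frame(child = c("A", "A", "B", "C"),
                      parent = c("B", "C", "R", "R"),
                      relation = c("is_a", "part_of", "part_of", "is_a"))
  dag <- ontology_dag(edges, "MF")
  s <- term_ancestry(dag, "A")$s_value
  expect_equal(s[["B"]], 0.8)
  expect_equal(s[["C"]], 0.6)
  expect_equal(s[["R"]], max(0.8 * 0.6, 0.6 * 0.8))
})

test_that("term similarity matches hand-computed values and is symmetric and bounded", {
  dag <- two_node_dag()
  expect_identical(sim_go(dag, "A", "A"), 1)
  expect_equal(sim_go(dag, "A", "R"), (0.8 + 1) / (1.8 + 1), tolerance = 1e-12)
  sib <- ontology_dag(data.frame(child = c("A", "B"), parent = "R",
                                 relation = "is_a"), "MF")
  expect_equal(sim_go(sib, "A", "B"), (0.8 + 0.8) / (1.8 + 1.8),
               tolerance = 1e-12)
  expect_equal(sim_go(sib, "A", "B"), sim_go(sib, "B", "A"))
  expect_error(sim_go(dag, "A", "NOPE"), "NOPE")

  set.seed(11)
  for (rep in 1:10) {
    dag <- ontology_dag(random_dag_edges(sample(4:10, 1)), "BP")
    pair <- sample(dag$terms, 2)
    s12 <- sim_go(dag, pair[1], pair[2])
    expect_identical(s12, sim_go(dag, pair[2], pair[1]))
    expect_gte(s12, 0)
    expect_lte(s12, 1)
  }
})

test_that("similarity is 1 only for identical terms on tree-shaped DAGs", {
  set.seed(3)
  for (rep in 1:5) {
    dag <- ontology_dag(random_dag_edges(8, extra_p = 0), "CC")
    for (i in 1:5) {
      pair <- sample(dag$terms, 2)
      expect_lt(sim_go(dag, pair[1], pair[2]), 1)
    }
    expect_identical(sim_go(dag, dag$terms[3], dag$terms[3]), 1)
  }
})

test_that("cached and fresh similarity computations agree exactly", {
  set.seed(5)
  edges <- random_dag_edges(10)
  dag1 <- ontology_dag(edges, "MF")
  pairs <- t(replicate(8, sample(dag1$terms, 2)))
  warm <- apply(pairs, 1, function(p) sim_go(dag1, p[1], p[2]))
  again <- apply(pairs, 1, function(p) sim_go(dag1, p[1], p[2]))  # cache hits
  fresh <- apply(pairs, 1, function(p) {
    sim_go(ontology_dag(edges, "MF"), p[1], p[2])
  })
  expect_identical(warm, again)
  expect_identical(warm, fresh)
  # matrix route agrees with scalar route
  m <- term_sim_matrix(dag1, dag1$terms[1:4])
  for (i in 1:4) for (j in 1:4)
    expect_identical(m[i, j], sim_go(dag1, dag1$terms[i], dag1$terms[j]))
})

test_that("dynamic-programming S-values match brute-force path enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    edges <- random_dag_edges(sample(5:12, 1))
    dag <- ontology_dag(edges, "BP")
    focus <- sample(dag$terms, 1)
    mine <- term_ancestry(dag, focus)$s_value
    oracle <- oracle_svalues(edges, focus)
    expect_setequal(names(mine), names(oracle))
    expect_equal(mine[names(oracle)], oracle, tolerance = 1e-14)
  }
})
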