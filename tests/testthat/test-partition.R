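test_that("positive representative is the centroid (or unit-norm) of P", {
  v <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(positive_representative(v), c(0.5, 0.5))
  expect_equal(positive_representative(v, norm = "unit"),
               c(1, 1) / sqrt(2), tolerance = 1e-12)
  single <- matrix(c(3, 4), 1)
  expect_equal(positive_representative(single), c(3, 4))
  expect_equal(positive_representative(single, norm = "unit"), c(0.6, 0.8))
  expect_error(positive_representative(matrix(0, 2, 2)), "zero norm")
  expect_error(positive_representative(matrix(numeric(0), 0, 2)), "empty")
})

test_that("reliable negatives are the genes strictly beyond the mean distance", {
  u <- matrix(c(0, 0.9, 2.5), ncol = 1,
              dimnames = list(c("a", "b", "c"), NULL))
  rn <- extract_reliable_negatives(1, u)
  expect_setequal(as.character(rn), c("a", "c"))   # distances 1, .1, 1.5; mean .8667
  expect_equal(attr(rn, "ave_dist"), mean(c(1, 0.1, 1.5)))
  # all genes identical to pr: strict inequality leaves RN empty
  same <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_length(as.character(extract_reliable_negatives(1, same)), 0)
  # a single unlabeled gene equals the mean, so never qualifies
  one <- matrix(5, 1, 1, dimnames = list("z", NULL))
  expect_length(as.character(extract_reliable_negatives(1, one)), 0)
})

test_that("similarity network keeps top-Q neighbors, symmetrized by union", {
  x <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  net <- build_similarity_network(x, q = 1)
  w <- net$w
  expect_true(isSymmetric(w))
  expect_identical(unname(diag(w)), rep(0, 3))
  expect_gt(w["a", "b"], 0)   # a keeps b, b keeps a
  expect_gt(w["b", "c"], 0)   # c keeps b (union symmetrization)
  expect_identical(w["a", "c"], 0)
  # identical genes have kernel weight exactly 1
  dup <- matrix(c(0, 0, 5), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(build_similarity_network(dup, q = 1)$w["a", "b"], 1)
  # two separated duplicate clusters with q = 1 stay disconnected
  cl <- matrix(c(0, 0, 9, 9), ncol = 1,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  wcl <- build_similarity_network(cl, q = 1)$w
  expect_identical(max(wcl[c("a", "b"), c("c", "d")]), 0)
  expect_warning(build_similarity_network(x, q = 5), "complete")
})

test_that("priors inject +1 per positive and balance RN mass to -|P|", {
  nodes <- sprintf("n%02d", 1:12)
  g0 <- init_priors(nodes[1:3], nodes[4:9], nodes)
  expect_identical(unname(g0[nodes[1:3]]), rep(1, 3))
  expect_equal(unname(g0[nodes[4:9]]), rep(-0.5, 6))  # -|P|/|RN| = -3/6
  expect_identical(unname(g0[nodes[10:12]]), rep(0, 3))
  expect_equal(sum(g0), 0, tolerance = 1e-12)
  g1 <- init_priors(nodes[1:4], nodes[5:8], nodes)
  expect_equal(unname(g1[nodes[5:8]]), rep(-1, 4))    # |P| = |RN|
  set.seed(9)
  for (rep in 1:10) {
    np <- sample(1:30, 1); nrn <- sample(1:40, 1)
    nds <- sprintf("x%03d", seq_len(np + nrn + 7))
    g <- init_priors(nds[1:np], nds[np + seq_len(nrn)], nds)
    expect_equal(sum(g[1:np]), np)
    expect_equal(sum(g[np + seq_len(nrn)]), -np, tolerance = 1e-12)
    expect_equal(sum(g), 0, tolerance = 1e-12)
  }
  expect_error(init_priors(nodes[1:3], character(0), nodes), "empty")
})

test_that("propagation matches closed forms on toy graphs", {
  # edgeless graph: S = 0, steady state is (1 - alpha) * G0
  w0 <- matrix(0, 3, 3)
  g0 <- c(1, -1, 0)
  s <- propagate_labels(w0, g0, alpha = 0.8)
  expect_equal(as.numeric(s), 0.2 * g0, tolerance = 1e-9)
  # two nodes, unit edge, priors (1, 0): (1-a)(I - aS)^-1 G0
  w2 <- matrix(c(0, 1, 1, 0), 2)
  s2 <- propagate_labels(w2, c(1, 0), alpha = 0.8, epsilon = 1e-12)
  expect_equal(as.numeric(s2), c(5, 4) / 9, tolerance = 1e-9)
  # alpha -> 0 limit returns the prior
  s3 <- propagate_labels(w2, c(1, 0), alpha = 1e-4)
  expect_equal(as.numeric(s3), c(1, 0), tolerance = 1e-3)
})

test_that("L1 update differences contract after the first iteration", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    w <- matrix(stats::runif(n * n) * (stats::runif(n * n) < 0.2), n, n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    g0 <- stats::rnorm(n)
    s <- propagate_labels(w, g0, alpha = 0.8, epsilon = 1e-10,
                          max_iter = 500)
    d <- attr(s, "deltas")
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("score partition applies the mirror mean-split rule", {
  sc <- c(a = 0.3, b = -0.1, c = -0.6)
  parts <- partition_unlabeled(sc)
  expect_identical(parts$lp, "a")
  expect_identical(parts$ln, "c")   # mean of non-positives is -0.35
  expect_identical(parts$wn, "b")
  # all-zero scores: nothing positive, everything at the non-positive mean
  z <- c(a = 0, b = 0)
  pz <- partition_unlabeled(z)
  expect_length(pz$lp, 0)
  expect_setequal(pz$ln, c("a", "b"))
  expect_length(pz$wn, 0)
  # explicit threshold 0 recovers the plain sign rule
  ps <- partition_unlabeled(sc, lp_threshold = 0)
  expect_identical(ps$lp, "a")
  # mixed positives: only the above-mean ones are likely positives
  m <- c(a = 1, b = 0.1, c = 0.2, d = -1)
  pm <- partition_unlabeled(m)
  expect_identical(pm$lp, "a")
  expect_true("b" %in% pm$wn && "c" %in% pm$wn)
})

test_that("full partitioning is exhaustive and disjoint on random data", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 60; d <- 8
    x <- matrix(stats::runif(n * d), n, d,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
    p <- rownames(x)[1:15]; u <- rownames(x)[16:n]
    part <- partition_genes(x, p, u, q_neighbors = 5)
    pieces <- list(part$rn, part$lp, part$ln, part$wn)
    expect_setequal(unlist(pieces), u)
    for (i in 1:3) for (j in (i + 1):4)
      expect_length(intersect(pieces[[i]], pieces[[j]]), 0)
    expect_identical(part$p, p)
  }
})

test_that("hidden positives score above true negatives on planted data", {
  st <- tiny_study(seed = 31)
  cfg <- tiny_config(st)
  study <- suppressMessages(load_study(cfg))
  run <- suppressMessages(run_pudi(cfg, study))
  sc <- run$partition$scores
  hid <- st$hidden_positives
  negs <- setdiff(study$unlabeled, hid)
  expect_gt(mean(sc[hid]), mean(sc[negs]))
})
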