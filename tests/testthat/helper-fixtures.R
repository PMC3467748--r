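# Shared fixtures: hand-built toy DAGs, random DAG generator, and an
# independent brute-force oracle for S-values / term similarity that
# enumerates every upward path instead of using the package's dynamic
# programming.

two_node_dag <- function(relation = "is_a") {
  ontology_dag(data.frame(child = "A", parent = "R", relation = relation),
               namespace = "MF")
}

# Random DAG on n terms: a tree backbone (every edge points to a lower index,
# so acyclicity is guaranteed) plus extra multi-parent edges.
random_dag_edges <- function(n_terms, extra_p = 0.3) {
  ids <- sprintf("T%02d", seq_len(n_terms))
  edges <- data.frame(child = character(0), parent = character(0),
                      relation = character(0))
  for (i in 2:n_terms) {
    parents <- sample.int(i - 1, 1)
    if (i > 2 && stats::runif(1) < extra_p)
      parents <- unique(c(parents, sample.int(i - 1, 1)))
    edges <- rbind(edges, data.frame(
      child = ids[i], parent = ids[parents],
      relation = sample(c("is_a", "part_of"), length(parents),
                        replace = TRUE)))
  }
  edges
}

# Oracle: S_A(t) = max over all directed paths A -> ... -> t of the product
# of edge weights along the path.
oracle_svalues <- function(edges, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  best <- new.env(parent = emptyenv())
  assign(term, 1, envir = best)
  walk <- function(t, prod) {
    up <- edges[edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(up))) {
      p <- up$parent[i]
      pr <- prod * weights[[up$relation[i]]]
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (pr > cur) assign(p, pr, envir = best)
      walk(p, pr)
    }
  }
  walk(term, 1)
  unlist(as.list(best))
}

oracle_sim <- function(edges, a, b, weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- oracle_svalues(edges, a, weights)
  sb <- oracle_svalues(edges, b, weights)
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

# Small synthetic study for fast end-to-end tests.
tiny_study <- function(seed = 1, rho = 0.25, ...) {
  generate_synthetic_study(n_genes = 80, n_positives = 24, rho = rho,
                           n_terms = c(BP = 15, MF = 15, CC = 15),
                           n_disease_terms = 4, n_domains = 12,
                           n_disease_domains = 3, ann_per_ns = 3,
                           domains_per_gene = 2,
                           ppi_background_p = 0.05, ppi_bias = 0.15,
                           seed = seed, ...)
}

tiny_config <- function(study, ...) {
  pudi_config_from_study(study, calibrate = FALSE, q_neighbors = 5, ...)
}

# Linearly separable 2-D toy with gene-style rownames.
separable_toy <- function(n = 40, gap = 1.5, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n, mean = gap), ncol = 2),
             matrix(stats::rnorm(n, mean = -gap), ncol = 2))
  rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
  colnames(x) <- c("f1", "f2")
  list(x = x, pos = rownames(x)[seq_len(n / 2)],
       neg = rownames(x)[(n / 2 + 1):n])
}
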