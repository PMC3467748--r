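#' Generate a synthetic disease-gene study
#'
#' Emulates the five inputs of a disease-gene identification study without
#' any download: a toy ontology (one random tree-shaped DAG per namespace,
#' mixing `is_a` and `part_of` edges), gene annotations enriched for a hidden
#' "disease term" subset among planted positives, Pfam-style domain
#' memberships with an analogous disease-domain subset, a PPI network with
#' elevated positive-positive edge probability, and positive / unlabeled gene
#' lists where a fraction `rho` of the planted positives is relabeled into the
#' unlabeled set as hidden positives (the recovery targets).
#'
#' All files are plain text in the package's standard formats and regeneration
#' with the same parameters and seed is byte-identical.
#'
#' @param dir output directory (created if missing).
#' @param n_genes total number of genes.
#' @param n_positives planted disease genes; after contamination
#'   `|P| = round((1 - rho) * n_positives)` remain visible.
#' @param rho contamination fraction in \[0,1): share of planted positives
#'   hidden inside the unlabeled set.
#' @param n_terms terms per namespace (named vector BP/MF/CC).
#' @param n_disease_terms size of the disease-term subset per namespace.
#' @param n_domains,n_disease_domains domain universe and disease subset sizes.
#' @param ann_per_ns annotations drawn per gene and namespace.
#' @param domains_per_gene domains drawn per gene.
#' @param enrichment_odds odds multiplier with which planted positives prefer
#'   disease terms/domains (1 = no signal).
#' @param ppi_background_p background edge probability.
#' @param ppi_bias extra positive-positive edge probability (0 = no signal).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `pudi_study`: list of file `paths` (obo,
#'   annotations, domains, ppi, positives, unlabeled, truth), the gene sets,
#'   and the generation `params`.
#' @export
generate_synthetic_study <- function(dir = tempfile("pudi_study_"),
                                     n_genes = 600, n_positives = 143,
                                     rho = 0.3,
                                     n_terms = c(BP = 60, MF = 60, CC = 60),
                                     n_disease_terms = 10,
                                     n_domains = 40, n_disease_domains = 8,
                                     ann_per_ns = 4, domains_per_gene = 2,
                                     enrichment_odds = 6,
                                     ppi_background_p = 0.01,
                                     ppi_bias = 0.08, seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n_positives < n_genes)
  if (n_disease_terms > min(n_terms) || n_disease_domains > n_domains)
    stop("disease subset larger than the term/domain universe")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  genes <- sprintf("G%04d", seq_len(n_genes))
  planted <- sort(sample(genes, n_positives))
  n_hidden <- round(rho * n_positives)
  hidden <- sort(sample(planted, n_hidden))
  visible_p <- setdiff(planted, hidden)
  unlabeled <- sort(setdiff(genes, visible_p))

  # --- ontology: one random tree per namespace, root = term 1
  obo_lines <- c("format-version: 1.2", "")
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  terms <- disease_terms <- list()
  for (ns in names(n_terms)) {
    nt <- n_terms[[ns]]
    ids <- sprintf("%s:%07d", ns, seq_len(nt))
    parent_idx <- c(NA, vapply(2:nt, function(i) sample.int(i - 1L, 1L),
                               integer(1)))
    relation <- c(NA, ifelse(stats::runif(nt - 1) < 0.75, "is_a", "part_of"))
    terms[[ns]] <- ids
    disease_terms[[ns]] <- sort(sample(ids[-1], n_disease_terms))
    for (i in seq_len(nt)) {
      obo_lines <- c(obo_lines, "[Term]", paste0("id: ", ids[i]),
                     paste0("name: ", tolower(ns), " term ", i),
                     paste0("namespace: ", ns_long[[ns]]))
      if (i > 1) {
        obo_lines <- c(obo_lines,
                       if (relation[i] == "is_a")
                         paste0("is_a: ", ids[parent_idx[i]])
                       else
                         paste0("relationship: part_of ", ids[parent_idx[i]]))
      }
      obo_lines <- c(obo_lines, "")
    }
  }

  weighted_draw <- function(pool, hot, k, odds) {
    w <- ifelse(pool %in% hot, odds, 1)
    sample(pool, k, prob = w)
  }

  # --- annotations
  ann <- list()
  for (g in genes) {
    is_pos <- g %in% planted
    for (ns in names(terms)) {
      drawn <- if (is_pos)
        weighted_draw(terms[[ns]], disease_terms[[ns]], ann_per_ns,
                      enrichment_odds)
      else sample(terms[[ns]], ann_per_ns)
      ann[[length(ann) + 1L]] <- data.frame(gene = g, term = sort(drawn),
                                            ns = ns)
    }
  }
  ann <- do.call(rbind, ann)

  # --- domains
  domain_ids <- sprintf("PF%05d", seq_len(n_domains))
  disease_domains <- sort(sample(domain_ids, n_disease_domains))
  dom <- do.call(rbind, lapply(genes, function(g) {
    drawn <- if (g %in% planted)
      weighted_draw(domain_ids, disease_domains, domains_per_gene,
                    enrichment_odds)
    else sample(domain_ids, domains_per_gene)
    data.frame(gene = g, domain = sort(drawn))
  }))

  # --- PPI: background G(n, p) plus extra positive-positive edges
  pairs <- utils::combn(genes, 2)
  is_pp <- pairs[1, ] %in% planted & pairs[2, ] %in% planted
  p_edge <- ppi_background_p + ifelse(is_pp, ppi_bias, 0)
  keep <- stats::runif(ncol(pairs)) < p_edge
  ppi <- data.frame(a = pairs[1, keep], b = pairs[2, keep])

  paths <- list(obo = file.path(dir, "ontology.obo"),
                annotations = file.path(dir, "annotations.tsv"),
                domains = file.path(dir, "domains.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                positives = file.path(dir, "positives.txt"),
                unlabeled = file.path(dir, "unlabeled.txt"),
                truth = file.path(dir, "truth.txt"))
  writeLines(obo_lines, paths$obo)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dom, paths$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ppi, paths$ppi, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(visible_p, paths$positives)
  writeLines(unlabeled, paths$unlabeled)
  writeLines(hidden, paths$truth)

  structure(list(paths = paths, positives = visible_p, unlabeled = unlabeled,
                 hidden_positives = hidden,
                 disease_terms = disease_terms,
                 disease_domains = disease_domains,
                 params = list(n_genes = n_genes, n_positives = n_positives,
                               rho = rho, n_terms = n_terms,
                               n_disease_terms = n_disease_terms,
                               n_domains = n_domains,
                               n_disease_domains = n_disease_domains,
                               ann_per_ns = ann_per_ns,
                               domains_per_gene = domains_per_gene,
                               enrichment_odds = enrichment_odds,
                               ppi_background_p = ppi_background_p,
                               ppi_bias = ppi_bias, seed = seed)),
            class = "pudi_study")
}

#' @export
print.pudi_study <- function(x, ...) {
  cat("pudi_study: ", x$params$n_genes, " genes, |P|=", length(x$positives),
      ", |U|=", length(x$unlabeled), " (", length(x$hidden_positives),
      " hidden positives, rho=", x$params$rho, "), seed=", x$params$seed,
      "\n", sep = "")
  invisible(x)
}
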