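#' @import igraph
NULL

.new_gene_record <- function(gene_id) {
  list(gene_id = gene_id,
       terms = list(BP = character(0), MF = character(0), CC = character(0)),
       domains = character(0))
}

#' Read a gene -> ontology-term annotation table
#'
#' Expects a headerless TSV with columns `gene_id`, `term_id`, `namespace`
#' (`BP`/`MF`/`CC` or the long `biological_process` style). Rows with an
#' unknown namespace are skipped with a warning; records are merged by gene.
#'
#' @param path annotation TSV path.
#' @param records optional existing record list to merge into.
#' @return named list of gene records (`gene_id`, per-namespace `terms`,
#'   `domains`).
#' @export
read_annotations <- function(path, records = list()) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty annotation file: ", path)
  if (ncol(df) < 3) stop("annotation file needs 3 columns: gene, term, namespace")
  ns <- .obo_namespace_map[as.character(df[[3]])]
  if (anyNA(ns)) {
    warning(sum(is.na(ns)), " annotation row(s) with unknown namespace skipped")
    df <- df[!is.na(ns), , drop = FALSE]
    ns <- ns[!is.na(ns)]
  }
  for (i in seq_len(nrow(df))) {
    g <- as.character(df[[1]][i])
    if (is.null(records[[g]])) records[[g]] <- .new_gene_record(g)
    records[[g]]$terms[[ns[i]]] <-
      unique(c(records[[g]]$terms[[ns[i]]], as.character(df[[2]][i])))
  }
  records
}

#' Read a gene -> protein-domain table
#'
#' Headerless TSV with columns `gene_id`, `domain_accession` (Pfam-A style).
#' Genes not yet seen get a fresh record with empty annotations.
#'
#' @inheritParams read_annotations
#' @return updated record list.
#' @export
read_domains <- function(path, records = list()) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty domain file: ", path)
  if (ncol(df) < 2) stop("domain file needs 2 columns: gene, domain")
  for (i in seq_len(nrow(df))) {
    g <- as.character(df[[1]][i])
    if (is.null(records[[g]])) records[[g]] <- .new_gene_record(g)
    records[[g]]$domains <- unique(c(records[[g]]$domains,
                                     as.character(df[[2]][i])))
  }
  records
}

#' Read an undirected PPI edge list
#'
#' Two-column TSV (or SIF with an interaction-type middle column) of gene id
#' pairs. Self-loops are removed and duplicate edges (either orientation)
#' collapsed.
#'
#' @param path edge-list path.
#' @return an undirected simple [igraph::graph].
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty PPI file: ", path)
  if (ncol(df) >= 3 && !any(df[[2]] %in% df[[1]])) {
    # SIF: node relation node
    el <- cbind(as.character(df[[1]]), as.character(df[[3]]))
  } else {
    el <- cbind(as.character(df[[1]]), as.character(df[[2]]))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a gene list (one id per line)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

.ppi_feature_names <- c("degree", "n1", "n2", "cluster")

#' Define a frozen feature space
#'
#' Fixes the ordered feature lists per category. All vectors assembled against
#' one feature space are positionally comparable. The four PPI topology
#' features are always part of the space.
#'
#' @param domains,mf,bp,cc character vectors of feature ids (domain accessions
#'   and ontology term ids); stored in the given order.
#' @return object of class `feature_space`.
#' @export
feature_space <- function(domains = character(0), mf = character(0),
                          bp = character(0), cc = character(0)) {
  structure(list(domains = as.character(domains), mf = as.character(mf),
                 bp = as.character(bp), cc = as.character(cc),
                 ppi = .ppi_feature_names),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space: ", length(x$domains), " domains + ",
      length(x$mf), " MF + ", length(x$bp), " BP + ", length(x$cc),
      " CC terms + 4 PPI features\n", sep = "")
  invisible(x)
}

#' @export
length.feature_space <- function(x) {
  length(x$domains) + length(x$mf) + length(x$bp) + length(x$cc) + 4L
}

#' Rebuild a feature space from prefixed feature names
#'
#' Inverse of the internal naming scheme (`D:`, `MF:`, `BP:`, `CC:`, `PPI:`
#' prefixes) used in feature matrices and stored in trained models; lets a
#' saved model featurize new genes against its own space.
#'
#' @param names character vector of prefixed feature names.
#' @return a [feature_space()].
#' @export
feature_space_from_names <- function(names) {
  strip <- function(prefix) sub(paste0("^", prefix, ":"), "",
                                grep(paste0("^", prefix, ":"), names,
                                     value = TRUE))
  feature_space(domains = strip("D"), mf = strip("MF"), bp = strip("BP"),
                cc = strip("CC"))
}

feature_names <- function(space) {
  c(if (length(space$domains)) paste0("D:", space$domains),
    if (length(space$mf)) paste0("MF:", space$mf),
    if (length(space$bp)) paste0("BP:", space$bp),
    if (length(space$cc)) paste0("CC:", space$cc),
    paste0("PPI:", space$ppi))
}

#' Candidate feature space from a study's data
#'
#' All domain accessions seen across the gene records plus all terms of each
#' loaded ontology DAG, each list sorted for a deterministic order.
#'
#' @param records gene record list.
#' @param dags named list of [ontology_dag()] (names among BP/MF/CC).
#' @return a [feature_space()].
#' @export
feature_space_from_study <- function(records, dags) {
  doms <- sort(unique(unlist(lapply(records, `[[`, "domains"))))
  feature_space(domains = doms,
                mf = if (!is.null(dags$MF)) sort(dags$MF$terms) else character(0),
                bp = if (!is.null(dags$BP)) sort(dags$BP$terms) else character(0),
                cc = if (!is.null(dags$CC)) sort(dags$CC$terms) else character(0))
}

#' Ontology component of a gene vector
#'
#' Entry j is the maximal term similarity between feature term j and any of
#' the gene's annotated terms in that namespace; all-zero when the gene has no
#' usable annotation there. Annotated terms absent from the DAG are skipped.
#'
#' @param record a gene record.
#' @param namespace `"BP"`, `"MF"` or `"CC"`.
#' @param feature_terms ordered term ids drawn from `dag`.
#' @param dag the namespace's [ontology_dag()].
#' @return numeric vector in \[0,1\]^`length(feature_terms)`.
#' @export
go_component <- function(record, namespace, feature_terms, dag) {
  gt <- record$terms[[namespace]]
  gt <- gt[gt %in% dag$terms]
  if (!length(gt) || !length(feature_terms))
    return(stats::setNames(numeric(length(feature_terms)), feature_terms))
  m <- term_sim_matrix(dag, gt, feature_terms)
  apply(m, 2, max)
}

# One gene x feature-term similarity matrix per namespace, shared by
# featurization and feature scoring. Annotated-but-unknown terms are counted
# and reported once.
.go_component_matrix <- function(records, namespace, feature_terms, dag) {
  genes <- names(records)
  out <- matrix(0, length(genes), length(feature_terms),
                dimnames = list(genes, feature_terms))
  if (!length(feature_terms)) return(out)
  all_ann <- unique(unlist(lapply(records, function(r) r$terms[[namespace]])))
  skipped <- setdiff(all_ann, dag$terms)
  if (length(skipped))
    message(length(skipped), " annotated ", namespace,
            " term(s) absent from the DAG; skipped")
  ann <- intersect(all_ann, dag$terms)
  if (!length(ann)) return(out)
  sim <- term_sim_matrix(dag, ann, feature_terms)
  for (g in genes) {
    gt <- intersect(records[[g]]$terms[[namespace]], ann)
    if (length(gt) == 1L) out[g, ] <- sim[gt, ]
    else if (length(gt) > 1L) out[g, ] <- apply(sim[gt, , drop = FALSE], 2, max)
  }
  out
}

#' Domain component of a gene vector
#'
#' Binary membership indicator over an ordered accession list.
#'
#' @param record a gene record.
#' @param domain_space ordered character vector of domain accessions.
#' @return 0/1 numeric vector.
#' @export
domain_component <- function(record, domain_space) {
  stats::setNames(as.numeric(domain_space %in% record$domains), domain_space)
}

.domain_matrix <- function(records, domain_space) {
  m <- matrix(0, length(records), length(domain_space),
              dimnames = list(names(records), domain_space))
  for (g in names(records))
    m[g, ] <- as.numeric(domain_space %in% records[[g]]$domains)
  m
}

#' PPI topological features
#'
#' For each queried gene: `degree` (neighbor count), `n1` (proportion of known
#' disease genes among direct neighbors), `n2` (same proportion over the
#' radius-2 neighborhood, excluding the gene itself), and `cluster` (local
#' clustering coefficient, 0 when degree < 2). Genes absent from the network
#' get all zeros.
#'
#' @param net undirected [igraph::graph] over gene ids.
#' @param gene_ids genes to query.
#' @param known_positives character vector of confirmed disease gene ids
#'   (restrict to the training fold to avoid label leakage).
#' @return numeric matrix `length(gene_ids)` x 4.
#' @export
ppi_topology <- function(net, gene_ids, known_positives = character(0)) {
  out <- matrix(0, length(gene_ids), 4,
                dimnames = list(gene_ids, .ppi_feature_names))
  vn <- igraph::V(net)$name
  present <- gene_ids[gene_ids %in% vn]
  if (!length(present)) return(out)
  deg <- igraph::degree(net, v = present)
  out[present, "degree"] <- deg
  nb1 <- igraph::adjacent_vertices(net, present)
  out[present, "n1"] <- vapply(seq_along(present), function(i) {
    nm <- nb1[[i]]$name
    if (!length(nm)) 0 else sum(nm %in% known_positives) / length(nm)
  }, numeric(1))
  nb2 <- igraph::ego(net, order = 2, nodes = present, mindist = 1)
  out[present, "n2"] <- vapply(seq_along(present), function(i) {
    nm <- nb2[[i]]$name
    if (!length(nm)) 0 else sum(nm %in% known_positives) / length(nm)
  }, numeric(1))
  cc <- igraph::transitivity(net, type = "local", vids = present,
                             isolates = "zero")
  cc[!is.finite(cc)] <- 0
  out[present, "cluster"] <- cc
  out
}

.scale_ppi <- function(ppi, ranges = NULL) {
  if (is.null(ranges))
    ranges <- list(min = apply(ppi, 2, min), max = apply(ppi, 2, max))
  span <- ranges$max - ranges$min
  scaled <- sweep(ppi, 2, ranges$min, "-")
  for (j in seq_len(ncol(scaled)))
    scaled[, j] <- if (span[j] > 0) scaled[, j] / span[j] else 0
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  attr(scaled, "ranges") <- ranges
  scaled
}

#' Assemble gene feature vectors
#'
#' Concatenates, per gene and in fixed order, the binary domain block, the
#' MF/BP/CC ontology-similarity blocks and the PPI topology block. The PPI
#' block is min-max scaled to \[0,1\] so it is commensurate with the other
#' blocks under Euclidean distance; pass `ppi_ranges` computed on training
#' genes when featurizing held-out genes (values are clipped to \[0,1\]).
#'
#' @param records gene record list.
#' @param space a [feature_space()].
#' @param dags named list of [ontology_dag()].
#' @param net PPI [igraph::graph].
#' @param known_positives confirmed disease genes for the `n1`/`n2` features.
#' @param ppi_ranges optional `list(min=, max=)` per PPI feature from a
#'   previous call (attribute `ppi_ranges` of its result).
#' @return numeric matrix genes x features with attributes `ppi_ranges` and
#'   `nonzero_fraction` (per-gene fraction of non-zero entries) and the
#'   feature space as attribute `space`.
#' @export
featurize_genes <- function(records, space, dags, net,
                            known_positives = character(0),
                            ppi_ranges = NULL) {
  stopifnot(inherits(space, "feature_space"))
  blocks <- list(.domain_matrix(records, space$domains))
  for (ns in c("mf", "bp", "cc")) {
    NS <- toupper(ns)
    blocks[[ns]] <- if (length(space[[ns]]) && !is.null(dags[[NS]]))
      .go_component_matrix(records, NS, space[[ns]], dags[[NS]])
    else matrix(0, length(records), length(space[[ns]]),
                dimnames = list(names(records), space[[ns]]))
  }
  ppi_raw <- ppi_topology(net, names(records), known_positives)
  ppi <- .scale_ppi(ppi_raw, ppi_ranges)
  x <- do.call(cbind, c(blocks, list(ppi)))
  colnames(x) <- feature_names(space)
  attr(x, "ppi_ranges") <- attr(ppi, "ranges")
  attr(x, "nonzero_fraction") <- rowMeans(x != 0)
  attr(x, "space") <- space
  x
}

#' Assemble a single gene's feature vector
#'
#' Convenience wrapper around [featurize_genes()] for one record.
#'
#' @inheritParams featurize_genes
#' @param record a single gene record.
#' @return named numeric vector.
#' @export
assemble_vector <- function(record, space, dags, net,
                            known_positives = character(0),
                            ppi_ranges = NULL) {
  recs <- stats::setNames(list(record), record$gene_id)
  featurize_genes(recs, space, dags, net, known_positives, ppi_ranges)[1, ]
}

#' Export a feature matrix as TSV
#'
#' Dense matrix with a `gene_id` column and a header row of feature names.
#'
#' @param x matrix from [featurize_genes()].
#' @param path output path.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
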