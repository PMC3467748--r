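#' Construct an ontology DAG
#'
#' Builds a directed acyclic graph of ontology terms from a child -> parent
#' edge table. Edges carry a semantic relation (`is_a` or `part_of`) whose
#' weight controls how much semantic contribution decays across the edge when
#' S-values are propagated (see [term_ancestry()]).
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`.
#' @param terms optional character vector of term ids; defaults to the union
#'   of terms appearing in `edges`. Terms not appearing in `edges` are kept as
#'   isolated roots.
#' @param edge_weights named numeric vector mapping relation kind to its
#'   per-edge contribution factor in (0,1). Defaults: `is_a` 0.8, `part_of` 0.6.
#' @return an object of class `ontology_dag` with elements `terms`, `edges`,
#'   `namespace`, `edge_weights`, and adjacency lists `parents` / `children`
#'   (named numeric vectors of edge weights).
#' @export
ontology_dag <- function(edges, namespace = c("BP", "MF", "CC"),
                         terms = NULL,
                         edge_weights = c(is_a = 0.8, part_of = 0.6)) {
  namespace <- match.arg(namespace)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  stopifnot(all(edge_weights > 0 & edge_weights < 1))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  bad <- !edges$relation %in% names(edge_weights)
  if (any(bad)) stop("unknown relation kind(s): ",
                     paste(unique(edges$relation[bad]), collapse = ", "))
  edges$weight <- unname(edge_weights[edges$relation])
  all_terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (!length(all_terms)) stop("ontology has no terms")

  cyc <- .find_cycle_terms(all_terms, edges)
  if (length(cyc)) {
    stop("cyclic term graph; terms involved in a cycle: ",
         paste(cyc, collapse = " -> "))
  }

  parents <- children <- stats::setNames(vector("list", length(all_terms)), all_terms)
  for (i in seq_len(nrow(edges))) {
    ch <- edges$child[i]; pa <- edges$parent[i]; w <- edges$weight[i]
    parents[[ch]] <- c(parents[[ch]], stats::setNames(w, pa))
    children[[pa]] <- c(children[[pa]], stats::setNames(w, ch))
  }

  structure(list(terms = all_terms, edges = edges, namespace = namespace,
                 edge_weights = edge_weights, parents = parents,
                 children = children, cache = new.env(parent = emptyenv())),
            class = "ontology_dag")
}

# Kahn's algorithm on child->parent edges; leftover nodes lie on a cycle.
.find_cycle_terms <- function(terms, edges) {
  if (!nrow(edges)) return(character(0))
  outdeg <- table(factor(edges$child, levels = terms))
  adj_in <- split(edges$child, factor(edges$parent, levels = terms))
  queue <- terms[outdeg == 0]
  removed <- logical(length(terms)); names(removed) <- terms
  outdeg <- as.numeric(outdeg); names(outdeg) <- terms
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    removed[t] <- TRUE
    for (ch in adj_in[[t]]) {
      outdeg[ch] <- outdeg[ch] - 1
      if (outdeg[ch] == 0 && !removed[ch]) queue <- c(queue, ch)
    }
  }
  names(removed)[!removed]
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag [", x$namespace, "]: ", length(x$terms), " terms, ",
      nrow(x$edges), " edges (",
      paste(names(x$edge_weights), x$edge_weights, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

.obo_namespace_map <- c(biological_process = "BP", molecular_function = "MF",
                        cellular_component = "CC",
                        BP = "BP", MF = "MF", CC = "CC")

#' Load an OBO ontology file
#'
#' Parses `[Term]` stanzas of an OBO 1.2 flat file into one [ontology_dag()]
#' per namespace. Only `is_a` and `part_of` relations are kept; other
#' relationship types (e.g. `regulates`) are dropped and their count reported.
#' Obsolete terms are excluded, together with any edge touching them.
#'
#' @param path path to the OBO file.
#' @param edge_weights see [ontology_dag()].
#' @return named list of `ontology_dag`, one per namespace present
#'   (names among `"BP"`, `"MF"`, `"CC"`).
#' @export
load_obo <- function(path, edge_weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path)
  # stanzas end at the next stanza header or EOF
  headers <- which(grepl("^\\[", lines))
  term_rows <- lapply(starts, function(s) {
    nxt <- headers[headers > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    block <- block[nzchar(block) & grepl(":", block, fixed = TRUE)]
    key <- sub("^([^:]+):.*$", "\\1", block)
    val <- sub("^[^:]+:\\s*", "", block)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    list(key = key, val = val)
  })

  dropped_rel <- 0L; obsolete <- character(0)
  term_ns <- character(0)
  edge_list <- list()
  for (tr in term_rows) {
    id <- tr$val[tr$key == "id"][1]
    if (is.na(id)) next
    if (any(tr$key == "is_obsolete" & tr$val == "true")) {
      obsolete <- c(obsolete, id); next
    }
    ns_raw <- tr$val[tr$key == "namespace"][1]
    ns <- .obo_namespace_map[ns_raw]
    if (is.na(ns)) {
      warning("term ", id, " has unknown namespace '", ns_raw, "'; skipped")
      next
    }
    term_ns[id] <- ns
    isa <- tr$val[tr$key == "is_a"]
    rel_raw <- tr$val[tr$key == "relationship"]
    rel_kind <- sub("^(\\S+)\\s+.*$", "\\1", rel_raw)
    rel_target <- sub("^\\S+\\s+", "", rel_raw)
    keep <- rel_kind == "part_of"
    dropped_rel <- dropped_rel + sum(!keep)
    if (length(isa) || any(keep)) {
      edge_list[[id]] <- data.frame(
        child = id,
        parent = c(isa, rel_target[keep]),
        relation = c(rep("is_a", length(isa)), rep("part_of", sum(keep))),
        stringsAsFactors = FALSE)
    }
  }
  if (dropped_rel > 0)
    warning(dropped_rel, " relationship edge(s) other than is_a/part_of dropped")

  edges <- if (length(edge_list)) do.call(rbind, edge_list) else
    data.frame(child = character(0), parent = character(0),
               relation = character(0))
  # drop edges touching obsolete or unparsed terms
  keep <- edges$child %in% names(term_ns) & edges$parent %in% names(term_ns)
  edges <- edges[keep, , drop = FALSE]

  out <- list()
  for (ns in unique(term_ns)) {
    ns_terms <- names(term_ns)[term_ns == ns]
    ns_edges <- edges[edges$child %in% ns_terms & edges$parent %in% ns_terms, ,
                      drop = FALSE]
    out[[ns]] <- ontology_dag(ns_edges, namespace = ns, terms = ns_terms,
                              edge_weights = edge_weights)
  }
  out
}

.ancestry_cached <- function(dag, term) {
  key <- paste0("anc:", term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- term_ancestry(dag, term)
  dag$cache[[key]] <- res
  res
}

#' S-values of a term and its ancestors
#'
#' For a focus term A, computes the set T_A of A plus all its ancestors, and
#' for each t in T_A the S-value S_A(t): the semantic contribution of t to A.
#' S_A(A) = 1 and S_A(t) = max over children t' of t inside T_A of
#' w_e(t' -> t) * S_A(t'), so contribution decays multiplicatively along the
#' best path from A up to t.
#'
#' @param dag an [ontology_dag()].
#' @param term focus term id.
#' @return object of class `term_ancestry`: list with `term`, `s_value`
#'   (named numeric over T_A), and `sv_total` = sum of the S-values.
#' @export
term_ancestry <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("unknown term: ", term)
  # upward closure
  seen <- term; frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(lapply(frontier, function(t) names(dag$parents[[t]]))))
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps); frontier <- ps
  }
  ta <- seen
  s <- stats::setNames(rep(NA_real_, length(ta)), ta)
  s[[term]] <- 1
  eval_s <- function(t) {
    if (!is.na(s[[t]])) return(s[[t]])
    ch <- dag$children[[t]]
    ch <- ch[names(ch) %in% ta]
    vals <- vapply(names(ch), eval_s, numeric(1))
    v <- max(ch * vals)
    s[[t]] <<- v
    v
  }
  for (t in ta) eval_s(t)
  structure(list(term = term, s_value = s, sv_total = sum(s)),
            class = "term_ancestry")
}

#' Semantic similarity between two ontology terms
#'
#' Wang-style DAG similarity: the S-values of the shared ancestry of A and B,
#' summed from both sides, over the total semantic values SV(A) + SV(B).
#' Symmetric, in \[0, 1\], and 1 for identical terms.
#'
#' @param dag an [ontology_dag()]; both terms must belong to it (similarity is
#'   only defined within one namespace).
#' @param a,b term ids.
#' @return similarity in \[0, 1\].
#' @export
sim_go <- function(dag, a, b) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!a %in% dag$terms) stop("unknown term: ", a)
  if (!b %in% dag$terms) stop("unknown term: ", b)
  key <- paste0("sim:", paste(sort(c(a, b)), collapse = "|"))
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  sa <- .ancestry_cached(dag, a)
  sb <- .ancestry_cached(dag, b)
  shared <- intersect(names(sa$s_value), names(sb$s_value))
  v <- (sum(sa$s_value[shared]) + sum(sb$s_value[shared])) /
    (sa$sv_total + sb$sv_total)
  dag$cache[[key]] <- v
  v
}

#' Pairwise term similarity matrix
#'
#' @param dag an [ontology_dag()].
#' @param terms_a,terms_b character vectors of term ids (default: `terms_a`).
#' @return numeric matrix `length(terms_a)` x `length(terms_b)` of [sim_go()]
#'   values, dimnames set to the term ids.
#' @export
term_sim_matrix <- function(dag, terms_a, terms_b = terms_a) {
  anc <- lapply(stats::setNames(unique(c(terms_a, terms_b)),
                                unique(c(terms_a, terms_b))),
                function(t) .ancestry_cached(dag, t))
  m <- matrix(0, length(terms_a), length(terms_b),
              dimnames = list(terms_a, terms_b))
  for (i in seq_along(terms_a)) {
    sa <- anc[[terms_a[i]]]
    for (j in seq_along(terms_b)) {
      sb <- anc[[terms_b[j]]]
      shared <- intersect(names(sa$s_value), names(sb$s_value))
      m[i, j] <- (sum(sa$s_value[shared]) + sum(sb$s_value[shared])) /
        (sa$sv_total + sb$sv_total)
    }
  }
  m
}

#' Dump a pairwise term-similarity matrix as TSV
#'
#' Debugging aid: writes `term_a<TAB>term_b<TAB>sim` rows for all unordered
#' term pairs (including self pairs).
#'
#' @param dag an [ontology_dag()].
#' @param terms term ids (default: all terms in the DAG).
#' @param path output file path.
#' @export
write_term_similarities <- function(dag, path, terms = dag$terms) {
  m <- term_sim_matrix(dag, terms)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(term_a = terms[idx[, 1]], term_b = terms[idx[, 2]],
                   sim = m[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
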