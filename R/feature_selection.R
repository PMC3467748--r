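#' Association score between a gene and a feature
#'
#' For an ontology feature, the maximal term similarity between the feature
#' term and the gene's annotated terms in the feature's namespace; for a
#' domain feature, binary membership.
#'
#' @param record a gene record.
#' @param feature feature id (term id or domain accession).
#' @param category one of `"D"`, `"MF"`, `"BP"`, `"CC"`.
#' @param dag the namespace [ontology_dag()] (ignored for `"D"`).
#' @return score in \[0, 1\].
#' @export
association_score <- function(record, feature, category, dag = NULL) {
  category <- as.character(category)
  if (category == "D") return(as.numeric(feature %in% record$domains))
  if (!category %in% c("MF", "BP", "CC"))
    stop("unknown feature category: ", category)
  gt <- record$terms[[category]]
  gt <- gt[gt %in% dag$terms]
  if (!length(gt)) return(0)
  max(vapply(gt, function(t) sim_go(dag, t, feature), numeric(1)))
}

#' Affinity frequency of a feature in a gene set
#'
#' Sum of the association scores of the feature over the genes; divided by the
#' set size when `normalize` is on (the default), so frequencies from sets of
#' different sizes are comparable.
#'
#' @param records list of gene records (the set P or U).
#' @param feature,category,dag see [association_score()].
#' @param normalize divide by the number of genes.
#' @return non-negative affinity frequency.
#' @export
affinity_frequency <- function(records, feature, category, dag = NULL,
                               normalize = TRUE) {
  if (!length(records)) {
    warning("affinity frequency of an empty gene set is 0")
    return(0)
  }
  s <- sum(vapply(records, association_score, numeric(1),
                  feature = feature, category = category, dag = dag))
  if (normalize) s / length(records) else s
}

#' Discrimination-ability score
#'
#' Scores how well a feature separates the positive set from the unlabeled
#' set: large when one affinity frequency is large and the other small,
#' relatively small when both are large or both small. Defined as
#' `max(af_p, af_u) * |af_p - af_u| / (af_p + af_u)`, with 0 when both
#' frequencies are 0.
#'
#' @param af_p,af_u non-negative affinity frequencies in P and U (vectorized).
#' @return non-negative score(s).
#' @export
discrimination_score <- function(af_p, af_u) {
  if (any(af_p < 0) || any(af_u < 0))
    stop("affinity frequencies must be non-negative")
  tot <- af_p + af_u
  ifelse(tot == 0, 0, pmax(af_p, af_u) * abs(af_p - af_u) / tot)
}

#' Score all candidate features for discrimination ability
#'
#' Computes, for every domain/MF/BP/CC feature of a candidate space, its
#' affinity frequency in the positive and in the unlabeled set and the
#' discrimination-ability score.
#'
#' @param records gene record list covering `positives` and `unlabeled`.
#' @param positives,unlabeled character vectors of gene ids.
#' @param space candidate [feature_space()].
#' @param dags named list of [ontology_dag()].
#' @param normalize see [affinity_frequency()].
#' @return data.frame with columns `feature`, `category`, `af_p`, `af_u`, `da`.
#' @export
score_features <- function(records, positives, unlabeled, space, dags,
                           normalize = TRUE) {
  stopifnot(all(positives %in% names(records)),
            all(unlabeled %in% names(records)))
  sub <- records[c(positives, unlabeled)]
  blocks <- list(D = .domain_matrix(sub, space$domains))
  for (cat in c("MF", "BP", "CC")) {
    feats <- space[[tolower(cat)]]
    blocks[[cat]] <- if (length(feats) && !is.null(dags[[cat]]))
      .go_component_matrix(sub, cat, feats, dags[[cat]])
    else matrix(0, length(sub), length(feats),
                dimnames = list(names(sub), feats))
  }
  out <- do.call(rbind, lapply(names(blocks), function(cat) {
    m <- blocks[[cat]]
    if (!ncol(m)) return(NULL)
    af_p <- colSums(m[positives, , drop = FALSE])
    af_u <- colSums(m[unlabeled, , drop = FALSE])
    if (normalize) {
      af_p <- af_p / length(positives)
      af_u <- af_u / length(unlabeled)
    }
    data.frame(feature = colnames(m), category = cat, af_p = af_p,
               af_u = af_u, da = discrimination_score(af_p, af_u),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Keep the top-N features per category
#'
#' Restricts a feature space to the N highest discrimination-ability features
#' in each of D, MF, BP and CC independently; ties at the cutoff are broken
#' by lexicographic feature id so selection is deterministic. Categories
#' smaller than N are kept whole. The four PPI features are always retained.
#'
#' @param scores data.frame from [score_features()].
#' @param n features to keep per category (default 1000).
#' @return the restricted [feature_space()].
#' @export
select_top_n <- function(scores, n = 1000) {
  stopifnot(n >= 1)
  pick <- function(cat) {
    s <- scores[scores$category == cat, , drop = FALSE]
    if (!nrow(s)) return(character(0))
    if (nrow(s) <= n) {
      if (nrow(s) < n)
        message("category ", cat, " has only ", nrow(s),
                " features; keeping all")
      return(sort(s$feature))
    }
    s <- s[order(-s$da, s$feature), , drop = FALSE]
    sort(s$feature[seq_len(n)])
  }
  feature_space(domains = pick("D"), mf = pick("MF"), bp = pick("BP"),
                cc = pick("CC"))
}

#' Export feature scores as TSV
#'
#' Writes `feature`, `category`, `af_p`, `af_u`, `da` and a `selected` flag;
#' the selection is reproducible from this file.
#'
#' @param scores data.frame from [score_features()].
#' @param selected a [feature_space()] from [select_top_n()].
#' @param path output path.
#' @export
write_feature_scores <- function(scores, selected, path) {
  kept <- c(selected$domains, selected$mf, selected$bp, selected$cc)
  scores$selected <- as.integer(scores$feature %in% kept)
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
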