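#' Positive representative vector
#'
#' Component-wise sum of the positive gene vectors, normalized: the class
#' representative against which unlabeled genes are screened by Euclidean
#' distance. With `norm = "mean"` (default) the sum is divided by the number
#' of positives, giving the class centroid — it lives on the same scale as
#' the gene vectors, so the distance screen measures dissimilarity to the
#' positive class rather than a gene's own vector norm. `norm = "unit"`
#' rescales the sum to unit Euclidean length instead; because typical gene
#' vectors have much larger norms, distances to a unit representative are
#' dominated by the gene's norm, which defeats the screen's purpose.
#'
#' @param p_vectors numeric matrix, one row per positive gene.
#' @param norm `"mean"` (centroid) or `"unit"` (unit Euclidean length).
#' @return numeric representative vector.
#' @export
positive_representative <- function(p_vectors, norm = c("mean", "unit")) {
  norm <- match.arg(norm)
  p_vectors <- rbind(p_vectors)
  if (!nrow(p_vectors)) stop("positive set is empty")
  v <- colSums(p_vectors)
  if (all(v == 0))
    stop("positive representative has zero norm (all-zero vectors)")
  if (norm == "mean") v / nrow(p_vectors) else v / sqrt(sum(v^2))
}

#' Extract reliable negatives from the unlabeled set
#'
#' Unlabeled genes whose Euclidean distance to the positive representative
#' vector is strictly greater than the average distance over all unlabeled
#' genes are taken as reliable negatives: they are far enough from the
#' positive class to be safely treated as negative training examples.
#'
#' @param pr positive representative vector.
#' @param u_vectors numeric matrix of unlabeled gene vectors (rownames = ids).
#' @return character vector of reliable-negative gene ids, with the average
#'   distance as attribute `ave_dist` and all distances as attribute `dist`.
#' @export
extract_reliable_negatives <- function(pr, u_vectors) {
  u_vectors <- rbind(u_vectors)
  if (!nrow(u_vectors)) stop("unlabeled set is empty")
  d <- sqrt(rowSums(sweep(u_vectors, 2, pr)^2))
  ave <- mean(d)
  rn <- rownames(u_vectors)[d > ave]
  structure(rn %||% character(0), ave_dist = ave, dist = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a top-Q gene similarity network
#'
#' Pairwise similarity `W_ij = exp(-||v_i - v_j||^2 / (2 sigma^2))` with the
#' kernel bandwidth defaulting to the median non-zero pairwise distance. Each
#' gene keeps only its Q most similar neighbors; the kept neighborhoods are
#' symmetrized by union so W stays symmetric. Diagonal is zero.
#'
#' @param vectors numeric matrix of gene vectors over P and U (rownames = ids).
#' @param q neighbors retained per gene (default 10).
#' @param sigma kernel bandwidth; `NULL` for the median-distance heuristic.
#' @return list of class `similarity_network`: `w` (dense symmetric matrix),
#'   `nodes`, `q`, `sigma`.
#' @export
build_similarity_network <- function(vectors, q = 10, sigma = NULL) {
  stopifnot(nrow(vectors) >= 2, q >= 1)
  n <- nrow(vectors)
  if (q >= n - 1)
    warning("q >= number of other genes; the network is complete")
  d <- as.matrix(stats::dist(vectors))
  if (is.null(sigma)) {
    nz <- d[upper.tri(d)]
    nz <- nz[nz > 0]
    sigma <- if (length(nz)) stats::median(nz) else 1
  }
  w <- exp(-d^2 / (2 * sigma^2))
  diag(w) <- 0
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(-w[i, ], rownames(vectors))  # ties by id for determinism
    keep[i, ord[seq_len(min(q, n - 1))]] <- TRUE
  }
  keep <- keep | t(keep)
  w <- w * keep
  dimnames(w) <- list(rownames(vectors), rownames(vectors))
  structure(list(w = w, nodes = rownames(vectors), q = q, sigma = sigma),
            class = "similarity_network")
}

#' Initial prior vector for label propagation
#'
#' +1 on every positive (sum +|P|), -|P|/|RN| on every reliable negative
#' (sum -|P|), 0 elsewhere, so both labeled sets inject equal and opposite
#' total prior mass and the vector sums to zero.
#'
#' @param positives,reliable_negatives,nodes character vectors of gene ids.
#' @return named numeric prior vector over `nodes`.
#' @export
init_priors <- function(positives, reliable_negatives, nodes) {
  if (!length(reliable_negatives))
    stop("reliable negative set is empty; loosen the distance threshold ",
         "used for reliable-negative extraction")
  stopifnot(all(positives %in% nodes), all(reliable_negatives %in% nodes))
  g0 <- stats::setNames(numeric(length(nodes)), nodes)
  g0[positives] <- 1
  g0[reliable_negatives] <- -length(positives) / length(reliable_negatives)
  g0
}

#' Random-walk label propagation to a steady state
#'
#' Iterates `G_r = alpha * S %*% G_{r-1} + (1 - alpha) * G_0` with
#' `S = D^-1/2 W D^-1/2` (`D` the diagonal degree matrix; rows of isolated
#' nodes are zero), until the L1 change drops below `epsilon` or `max_iter`
#' is reached. `alpha` weights neighbor influence against the prior.
#'
#' @param net a [build_similarity_network()] result, or a symmetric
#'   non-negative weight matrix.
#' @param g0 prior vector from [init_priors()].
#' @param alpha propagation weight in (0,1), default 0.8.
#' @param epsilon L1 convergence threshold, default 1e-6.
#' @param max_iter iteration cap, default 1000.
#' @return named numeric steady-state score vector with attributes
#'   `iterations` and `converged`.
#' @export
propagate_labels <- function(net, g0, alpha = 0.8, epsilon = 1e-6,
                             max_iter = 1000) {
  stopifnot(alpha > 0, alpha < 1)
  w <- if (inherits(net, "similarity_network")) net$w else net
  stopifnot(nrow(w) == length(g0))
  deg <- rowSums(w)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  s <- w * (dinv %o% dinv)
  g <- g0
  iter <- 0L
  converged <- FALSE
  deltas <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    g_new <- alpha * as.numeric(s %*% g) + (1 - alpha) * g0
    delta <- sum(abs(g_new - g))
    deltas[iter] <- delta
    g <- g_new
    if (delta < epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("label propagation did not converge within ", max_iter,
            " iterations")
  names(g) <- names(g0)
  attr(g, "iterations") <- iter
  attr(g, "converged") <- converged
  attr(g, "deltas") <- deltas
  g
}

#' Partition the remaining unlabeled genes by propagation score
#'
#' Mirror-image mean splits on the two sides of zero. Likely positives (LP)
#' are the genes whose score is at or above the mean of the positive scores
#' — the ones that stand out among the positively scored. Likely negatives
#' (LN) are the genes at or below the mean of the non-positive scores. The
#' remainder — weakly positive or weakly negative — forms the weak negative
#' set (WN), the least-trusted negative evidence. The three sets are disjoint
#' and exhaust the input.
#'
#' @param scores named numeric scores over U minus RN.
#' @param lp_threshold `NULL` (default) for the mean-of-positive-scores rule
#'   (LP = scores `>=` the mean; empty when no score is positive); a number
#'   for a fixed cut (LP = scores strictly `>` it, so `0` gives the plain
#'   sign rule).
#' @param ln_threshold score at or below which a non-LP gene is likely
#'   negative; `NULL` (default) uses the mean of the non-positive scores.
#' @return list with character vectors `lp`, `ln`, `wn` and the thresholds.
#' @export
partition_unlabeled <- function(scores, lp_threshold = NULL,
                                ln_threshold = NULL) {
  stopifnot(all(is.finite(scores)))
  ids <- names(scores)
  if (is.null(lp_threshold)) {
    pos <- scores[scores > 0]
    lp_threshold <- if (length(pos)) mean(pos) else Inf
    lp <- ids[scores >= lp_threshold]
  } else {
    lp <- ids[scores > lp_threshold]
  }
  rest <- scores[setdiff(ids, lp)]
  if (is.null(ln_threshold)) {
    nonpos <- scores[scores <= 0]
    ln_threshold <- if (length(nonpos)) mean(nonpos) else -Inf
  }
  ln <- names(rest)[rest <= ln_threshold]
  wn <- setdiff(names(rest), ln)
  list(lp = lp, ln = ln, wn = wn,
       thresholds = list(lp = lp_threshold, ln = ln_threshold))
}

#' Partition the unlabeled gene set into RN / LP / LN / WN
#'
#' Full partitioning stage: extracts reliable negatives by distance to the
#' positive representative, builds the top-Q similarity network over all
#' genes, propagates signed priors to a steady state, and splits the
#' remaining unlabeled genes by score.
#'
#' @param vectors feature matrix over P and U (rownames = gene ids).
#' @param positives,unlabeled character vectors of gene ids (rows of
#'   `vectors`).
#' @param q_neighbors,sigma see [build_similarity_network()].
#' @param alpha,epsilon,max_iter see [propagate_labels()].
#' @return object of class `pudi_partition`: gene-id sets `p`, `rn`, `lp`,
#'   `ln`, `wn`, per-gene `scores`, and the `thresholds`/network parameters
#'   used.
#' @export
partition_genes <- function(vectors, positives, unlabeled, q_neighbors = 10,
                            alpha = 0.8, epsilon = 1e-6, max_iter = 1000,
                            sigma = NULL) {
  stopifnot(all(positives %in% rownames(vectors)),
            all(unlabeled %in% rownames(vectors)))
  pr <- positive_representative(vectors[positives, , drop = FALSE])
  rn <- extract_reliable_negatives(pr, vectors[unlabeled, , drop = FALSE])
  ave_dist <- attr(rn, "ave_dist")
  rn <- as.character(rn)
  if (!length(rn))
    stop("no reliable negatives found; loosen the distance threshold ",
         "or check that the unlabeled set is heterogeneous")
  net <- build_similarity_network(vectors[c(positives, unlabeled), ,
                                          drop = FALSE],
                                  q = q_neighbors, sigma = sigma)
  g0 <- init_priors(positives, rn, net$nodes)
  scores <- propagate_labels(net, g0, alpha = alpha, epsilon = epsilon,
                             max_iter = max_iter)
  remaining <- setdiff(unlabeled, rn)
  parts <- partition_unlabeled(scores[remaining])
  structure(list(p = positives, rn = rn, lp = parts$lp, ln = parts$ln,
                 wn = parts$wn, scores = scores,
                 thresholds = c(list(ave_dist = ave_dist), parts$thresholds),
                 q = net$q, sigma = net$sigma, alpha = alpha),
            class = "pudi_partition")
}

#' @export
print.pudi_partition <- function(x, ...) {
  cat("pudi_partition: |P|=", length(x$p), " |RN|=", length(x$rn),
      " |LP|=", length(x$lp), " |LN|=", length(x$ln),
      " |WN|=", length(x$wn), "\n", sep = "")
  invisible(x)
}

#' Export a partition as TSV
#'
#' Rows `gene_id<TAB>set<TAB>score` with set in P/RN/LP/LN/WN.
#'
#' @param partition a [partition_genes()] result.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  sets <- c(P = "p", RN = "rn", LP = "lp", LN = "ln", WN = "wn")
  df <- do.call(rbind, lapply(names(sets), function(lab) {
    ids <- partition[[sets[lab]]]
    if (!length(ids)) return(NULL)
    data.frame(gene_id = ids, set = lab,
               score = unname(partition$scores[ids]))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
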