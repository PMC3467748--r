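#' Per-subset misclassification penalty profile
#'
#' The multi-level SVM penalizes a wrongly classified training example by a
#' factor that reflects how much the example's label is trusted: confirmed
#' positives more than likely positives, and reliable negatives more than
#' likely negatives more than weak negatives. The orderings `c_p > c_lp` and
#' `c_rn > c_ln > c_wn` are enforced.
#'
#' @param c_p,c_lp,c_rn,c_ln,c_wn positive penalty factors for P, LP, RN, LN
#'   and WN examples.
#' @return object of class `penalty_profile`.
#' @export
penalty_profile <- function(c_p = 1.0, c_lp = 0.5, c_rn = 1.0, c_ln = 0.5,
                            c_wn = 0.25) {
  vals <- c(c_p = c_p, c_lp = c_lp, c_rn = c_rn, c_ln = c_ln, c_wn = c_wn)
  if (any(vals <= 0)) stop("penalty factors must be positive")
  if (!(c_p > c_lp)) stop("penalty ordering violated: need c_p > c_lp")
  if (!(c_rn > c_ln && c_ln > c_wn))
    stop("penalty ordering violated: need c_rn > c_ln > c_wn")
  structure(as.list(vals), class = "penalty_profile")
}

#' @export
print.penalty_profile <- function(x, ...) {
  cat(sprintf("penalty_profile: C_P=%g C_LP=%g C_RN=%g C_LN=%g C_WN=%g\n",
              x$c_p, x$c_lp, x$c_rn, x$c_ln, x$c_wn))
  invisible(x)
}

.kernel_matrix <- function(x, y = x, kernel = "linear", gamma = NULL) {
  if (kernel == "linear") return(x %*% t(y))
  if (kernel == "rbf") {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
    d2[d2 < 0] <- 0
    return(exp(-gamma * d2))
  }
  stop("unsupported kernel: ", kernel)
}

# Soft-margin SVM dual with per-example box constraints 0 <= alpha_i <= C_i,
# solved as a QP. Returns alpha and the bias b.
.solve_weighted_svm <- function(k, y, c_vec) {
  n <- length(y)
  h <- (y %*% t(y)) * k
  diag(h) <- diag(h) + 1e-8  # numerical ridge
  sol <- kernlab::ipop(c = rep(-1, n), H = h, A = t(y), b = 0, r = 0,
                       l = rep(0, n), u = c_vec, maxiter = 200)
  alpha <- kernlab::primal(sol)
  alpha <- pmin(pmax(alpha, 0), c_vec)
  f0 <- as.numeric(k %*% (alpha * y))
  tol <- 1e-6 * max(c_vec)
  free <- alpha > tol & alpha < c_vec - tol
  if (any(free)) {
    b <- mean(y[free] - f0[free])
  } else {
    # no margin SVs: pick b minimizing the weighted hinge loss
    obj <- function(b) sum(c_vec * pmax(0, 1 - y * (f0 + b)))
    rng <- range(y - f0)
    b <- stats::optimize(obj, interval = rng + c(-1, 1))$minimum
  }
  list(alpha = alpha, b = b, status = kernlab::how(sol))
}

#' Train the multi-level weighted soft-margin SVM
#'
#' Trains one decision function on all five gene sets: P and LP on the
#' positive side, RN, LN and WN on the negative side, with each example's
#' misclassification penalty taken from its set's factor in the
#' [penalty_profile()]. The objective is the usual soft margin
#' `0.5 ||w||^2 + sum_i C_set(i) xi_i`, solved exactly in the dual.
#' Optionally fits a monotone sigmoid probability calibration on out-of-fold
#' decision scores of P (positive) vs RN (negative).
#'
#' @param vectors feature matrix containing rows for every gene in the
#'   partition sets.
#' @param partition a [partition_genes()] result (or any list with character
#'   elements `p`, `rn`, `lp`, `ln`, `wn`).
#' @param profile a [penalty_profile()].
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param gamma RBF width; default `1/ncol(vectors)`.
#' @param calibrate fit the probability calibration map (default TRUE).
#' @param calib_folds folds used to obtain out-of-fold calibration scores.
#' @param seed seed for the calibration fold split.
#' @return object of class `pudi_model`.
#' @export
train_weighted_svm <- function(vectors, partition, profile = penalty_profile(),
                               kernel = c("linear", "rbf"), gamma = NULL,
                               calibrate = TRUE, calib_folds = 3, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(profile, "penalty_profile"))
  sets <- list(p = partition$p, lp = partition$lp, rn = partition$rn,
               ln = partition$ln, wn = partition$wn)
  if (!length(sets$p)) stop("positive set is empty")
  if (!length(sets$rn)) stop("reliable negative set is empty")
  ids <- unlist(sets, use.names = FALSE)
  stopifnot(all(ids %in% rownames(vectors)))
  x <- vectors[ids, , drop = FALSE]
  y <- c(rep(1, length(sets$p)), rep(1, length(sets$lp)),
         rep(-1, length(sets$rn)), rep(-1, length(sets$ln)),
         rep(-1, length(sets$wn)))
  c_vec <- c(rep(profile$c_p, length(sets$p)),
             rep(profile$c_lp, length(sets$lp)),
             rep(profile$c_rn, length(sets$rn)),
             rep(profile$c_ln, length(sets$ln)),
             rep(profile$c_wn, length(sets$wn)))
  if (length(unique(y)) < 2) stop("training data has a single class")
  if (kernel == "rbf" && is.null(gamma)) gamma <- 1 / ncol(x)
  k <- .kernel_matrix(x, kernel = kernel, gamma = gamma)
  fit <- .solve_weighted_svm(k, y, c_vec)

  model <- structure(list(kernel = kernel, gamma = gamma, profile = profile,
                          alpha = fit$alpha, y = y, b = fit$b, x = x,
                          feature_names = colnames(vectors),
                          calibration = NULL, version = "pudi-model/1"),
                     class = "pudi_model")

  if (calibrate) {
    model$calibration <- .fit_calibration(vectors, partition, profile, kernel,
                                          gamma, calib_folds, seed)
  }
  model
}

#' Decision values of a trained model
#'
#' @param model a `pudi_model`.
#' @param vectors feature matrix over the genes to score.
#' @return named numeric decision scores.
#' @export
decision_values <- function(model, vectors) {
  if (!identical(colnames(vectors), model$feature_names))
    stop("feature space mismatch between model and input vectors")
  k <- .kernel_matrix(rbind(vectors), model$x, kernel = model$kernel,
                      gamma = model$gamma)
  stats::setNames(as.numeric(k %*% (model$alpha * model$y) + model$b),
                  rownames(vectors))
}

# Monotone sigmoid (Platt-style) calibration on out-of-fold scores of P vs RN.
.fit_calibration <- function(vectors, partition, profile, kernel, gamma,
                             folds, seed) {
  p <- partition$p; rn <- partition$rn
  folds <- max(2L, min(folds, length(p), length(rn)))
  assign_p <- .seeded_folds(length(p), folds, seed)
  assign_rn <- .seeded_folds(length(rn), folds, seed + 1L)
  scores <- labs <- numeric(0)
  for (f in seq_len(folds)) {
    held_p <- p[assign_p == f]; held_rn <- rn[assign_rn == f]
    sub <- list(p = setdiff(p, held_p), rn = setdiff(rn, held_rn),
                lp = partition$lp, ln = partition$ln, wn = partition$wn)
    if (!length(sub$p) || !length(sub$rn)) next
    m <- train_weighted_svm(vectors, sub, profile, kernel = kernel,
                            gamma = gamma, calibrate = FALSE)
    held <- c(held_p, held_rn)
    if (!length(held)) next
    scores <- c(scores, decision_values(m, vectors[held, , drop = FALSE]))
    labs <- c(labs, rep(1, length(held_p)), rep(0, length(held_rn)))
  }
  if (length(unique(labs)) < 2) return(c(a = 0, b = 1))
  fit <- suppressWarnings(
    stats::glm(labs ~ scores, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] <= 0) return(c(a = 0, b = 1))
  c(a = unname(co[1]), b = unname(co[2]))
}

.seeded_folds <- function(n, k, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Predict disease-gene labels
#'
#' Labels a gene `disease` when its decision score is strictly positive
#' (a score of exactly zero is non-disease), and maps scores to
#' probabilities through the model's monotone calibration, so ranking by
#' probability equals ranking by score.
#'
#' @param object a `pudi_model`.
#' @param vectors feature matrix over the genes to score.
#' @param ... unused.
#' @return data.frame with `gene_id`, `label`, `score`, `probability`.
#' @export
predict.pudi_model <- function(object, vectors, ...) {
  s <- decision_values(object, vectors)
  cal <- object$calibration %||% c(a = 0, b = 1)
  data.frame(gene_id = names(s),
             label = ifelse(s > 0, "disease", "non-disease"),
             score = unname(s),
             probability = unname(stats::plogis(cal["a"] + cal["b"] * s)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pudi_model <- function(x, ...) {
  cat("pudi_model (", x$kernel, " kernel): ", nrow(x$x),
      " training genes, ", sum(x$alpha > 1e-6), " support vectors\n", sep = "")
  print(x$profile)
  invisible(x)
}

#' Default penalty grid
#'
#' A small feasible grid over the five penalty factors, every row respecting
#' the orderings `c_p > c_lp` and `c_rn > c_ln > c_wn`.
#'
#' @return data.frame of candidate profiles.
#' @export
default_penalty_grid <- function() {
  g <- expand.grid(c_p = c(1, 2), c_lp = c(0.3, 0.5),
                   c_rn = c(0.5, 1), c_ln = c(0.25, 0.5),
                   c_wn = c(0.1, 0.25))
  g[g$c_p > g$c_lp & g$c_rn > g$c_ln & g$c_ln > g$c_wn, , drop = FALSE]
}

#' Select penalty factors by cross-validation
#'
#' Scores each feasible grid row by mean F-measure over k folds, training on
#' the partition with the held-out P (scored positive) and RN (scored
#' negative) genes removed. Ordering-violating rows are filtered before the
#' search; ties are broken toward smaller total C, then by row order. The
#' fold split is seeded, so the search is reproducible.
#'
#' @param vectors feature matrix over the partitioned genes.
#' @param partition a [partition_genes()] result.
#' @param grid data.frame with columns `c_p`, `c_lp`, `c_rn`, `c_ln`, `c_wn`.
#' @param folds number of folds (default 10; reduced if a set is smaller).
#' @param seed fold-split seed.
#' @param kernel,gamma see [train_weighted_svm()].
#' @return the selected [penalty_profile()], with the search table as
#'   attribute `search`.
#' @export
select_penalties <- function(vectors, partition, grid = default_penalty_grid(),
                             folds = 10, seed = 1L, kernel = "linear",
                             gamma = NULL) {
  ok <- grid$c_p > grid$c_lp & grid$c_rn > grid$c_ln & grid$c_ln > grid$c_wn
  if (any(!ok)) {
    message(sum(!ok), " ordering-violating grid row(s) filtered out")
    grid <- grid[ok, , drop = FALSE]
  }
  if (!nrow(grid)) stop("no feasible penalty profile in the grid")
  p <- partition$p; rn <- partition$rn
  folds <- max(2L, min(folds, length(p), length(rn)))
  assign_p <- .seeded_folds(length(p), folds, seed)
  assign_rn <- .seeded_folds(length(rn), folds, seed + 1L)
  mean_f <- vapply(seq_len(nrow(grid)), function(i) {
    prof <- penalty_profile(grid$c_p[i], grid$c_lp[i], grid$c_rn[i],
                            grid$c_ln[i], grid$c_wn[i])
    fs <- vapply(seq_len(folds), function(f) {
      held_p <- p[assign_p == f]; held_rn <- rn[assign_rn == f]
      sub <- list(p = setdiff(p, held_p), rn = setdiff(rn, held_rn),
                  lp = partition$lp, ln = partition$ln, wn = partition$wn)
      if (!length(sub$p) || !length(sub$rn) ||
          (!length(held_p) && !length(held_rn))) return(NA_real_)
      m <- train_weighted_svm(vectors, sub, prof, kernel = kernel,
                              gamma = gamma, calibrate = FALSE)
      held <- c(held_p, held_rn)
      pred <- decision_values(m, vectors[held, , drop = FALSE]) > 0
      truth <- c(rep(TRUE, length(held_p)), rep(FALSE, length(held_rn)))
      tp <- sum(pred & truth)
      prec <- if (sum(pred)) tp / sum(pred) else 0
      rec <- if (sum(truth)) tp / sum(truth) else 0
      f_measure(prec, rec)
    }, numeric(1))
    mean(fs, na.rm = TRUE)
  }, numeric(1))
  total_c <- rowSums(grid)
  best <- order(-mean_f, total_c)[1]
  prof <- penalty_profile(grid$c_p[best], grid$c_lp[best], grid$c_rn[best],
                          grid$c_ln[best], grid$c_wn[best])
  attr(prof, "search") <- cbind(grid, mean_f = mean_f)
  prof
}

#' Naive positive-vs-unlabeled SVM baseline
#'
#' Control classifier that treats every unlabeled gene as a negative and fits
#' a plain soft-margin SVM; the decision scores are oriented so that higher
#' means more disease-like.
#'
#' @param vectors feature matrix over P and U.
#' @param positives,unlabeled character vectors of gene ids.
#' @param cost soft-margin cost.
#' @return function of a feature matrix returning named decision scores.
#' @export
naive_svm_baseline <- function(vectors, positives, unlabeled, cost = 1) {
  x <- vectors[c(positives, unlabeled), , drop = FALSE]
  y <- factor(c(rep("pos", length(positives)), rep("neg", length(unlabeled))),
              levels = c("neg", "pos"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  train_dec <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                               "decision.values"))
  flip <- mean(train_dec[seq_along(positives)]) <
    mean(train_dec[-seq_along(positives)])
  function(newdata) {
    d <- as.numeric(attr(stats::predict(fit, rbind(newdata),
                                        decision.values = TRUE),
                         "decision.values"))
    if (flip) d <- -d
    stats::setNames(d, rownames(newdata))
  }
}

#' Serialize / restore a trained model
#'
#' Single-file serialization carrying a version tag, the feature names and
#' the penalty profile alongside the decision function.
#'
#' @param model a `pudi_model`.
#' @param path file path.
#' @return `read_pudi_model` returns the restored `pudi_model`.
#' @export
write_pudi_model <- function(model, path) {
  stopifnot(inherits(model, "pudi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pudi_model
#' @export
read_pudi_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pudi_model") || !identical(model$version, "pudi-model/1"))
    stop("not a pudi model file: ", path)
  model
}
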