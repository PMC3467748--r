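#' F-measure (harmonic mean of precision and recall)
#'
#' Accepts proportions in \[0,1\] or percentages (detected when any input
#' exceeds 1) and reports the result on the same scale. Zero when
#' `p + r = 0`.
#'
#' @param p,r precision and recall (vectorized).
#' @return F-measure on the input scale.
#' @export
f_measure <- function(p, r) {
  pct <- any(c(p, r) > 1)
  if (pct) {
    p <- p / 100
    r <- r / 100
  }
  if (any(p < 0 | p > 1 | r < 0 | r > 1))
    stop("precision/recall out of range")
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  if (pct) 100 * f else f
}

.prf <- function(truth, predicted_positive) {
  tp <- sum(truth & predicted_positive)
  p <- if (sum(predicted_positive)) tp / sum(predicted_positive) else 0
  r <- if (sum(truth)) tp / sum(truth) else 0
  c(precision = p, recall = r, f_measure = f_measure(p, r))
}

.auc <- function(truth, scores) {
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

.roc_points <- function(truth, scores) {
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

#' Study configuration
#'
#' Bundles input paths and the tunable parameters of the pipeline. Defaults:
#' top 1000 features per category, Q = 10 similarity-network neighbors,
#' propagation weight alpha = 0.8, convergence threshold epsilon = 1e-6,
#' 10 folds. `balance = TRUE` samples the unlabeled set down to `|P| = |U|`
#' (seeded).
#'
#' @param annotations,domains,ppi,positives,unlabeled input file paths (see
#'   the reader functions for formats); `obo` is the ontology path.
#' @param obo ontology OBO path.
#' @param n_top_features,q_neighbors,alpha,epsilon,max_iter,folds pipeline
#'   parameters.
#' @param balance sample U down to the size of P.
#' @param kernel,profile,penalty_grid classifier settings; a non-NULL
#'   `penalty_grid` triggers cross-validated penalty selection.
#' @param calibrate fit probability calibration.
#' @param normalize_af normalize affinity frequencies by set size.
#' @param seed seed for every stochastic step.
#' @return list of class `pudi_config`.
#' @export
pudi_config <- function(obo = NULL, annotations = NULL, domains = NULL,
                        ppi = NULL, positives = NULL, unlabeled = NULL,
                        n_top_features = 1000, q_neighbors = 10, alpha = 0.8,
                        epsilon = 1e-6, max_iter = 1000, folds = 10,
                        balance = FALSE, kernel = "linear",
                        profile = penalty_profile(), penalty_grid = NULL,
                        calibrate = TRUE, normalize_af = TRUE, seed = 1L) {
  structure(list(obo = obo, annotations = annotations, domains = domains,
                 ppi = ppi, positives = positives, unlabeled = unlabeled,
                 n_top_features = n_top_features, q_neighbors = q_neighbors,
                 alpha = alpha, epsilon = epsilon, max_iter = max_iter,
                 folds = folds, balance = balance, kernel = kernel,
                 profile = profile, penalty_grid = penalty_grid,
                 calibrate = calibrate, normalize_af = normalize_af,
                 seed = as.integer(seed)),
            class = "pudi_config")
}

#' @rdname pudi_config
#' @param study a `pudi_study` from [generate_synthetic_study()]; its file
#'   paths fill the corresponding config fields.
#' @param ... further arguments to [pudi_config()].
#' @export
pudi_config_from_study <- function(study, ...) {
  stopifnot(inherits(study, "pudi_study"))
  pudi_config(obo = study$paths$obo, annotations = study$paths$annotations,
              domains = study$paths$domains, ppi = study$paths$ppi,
              positives = study$paths$positives,
              unlabeled = study$paths$unlabeled, ...)
}

#' Load all study inputs
#'
#' Reads the ontology, annotation, domain, PPI and gene-list files of a
#' config; genes listed in P or U but absent from every table get empty
#' records. With `balance = TRUE` the unlabeled set is sampled down to the
#' positive set's size (seeded).
#'
#' @param config a [pudi_config()].
#' @return list with `records`, `dags`, `net`, `positives`, `unlabeled`.
#' @export
load_study <- function(config) {
  dags <- load_obo(config$obo)
  records <- read_annotations(config$annotations)
  records <- read_domains(config$domains, records)
  net <- read_ppi(config$ppi)
  positives <- read_gene_list(config$positives)
  unlabeled <- read_gene_list(config$unlabeled)
  if (length(common <- intersect(positives, unlabeled)))
    stop("gene(s) in both P and U: ", paste(utils::head(common), collapse = ", "))
  for (g in setdiff(c(positives, unlabeled), names(records)))
    records[[g]] <- .new_gene_record(g)
  if (isTRUE(config$balance) && length(unlabeled) > length(positives)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
    unlabeled <- sort(sample(unlabeled, length(positives)))
    message("balanced sampling: |U| reduced to ", length(unlabeled))
  }
  list(records = records, dags = dags, net = net, positives = positives,
       unlabeled = unlabeled)
}

#' Run the full PUDI pipeline
#'
#' Featurizes the genes, selects the top discriminating features, partitions
#' the unlabeled set into RN/LP/LN/WN by label propagation, trains the
#' multi-level weighted SVM and scores every unlabeled gene. Stage artifacts
#' and a run manifest are written when `out_dir` is given.
#'
#' @param config a [pudi_config()].
#' @param study optional preloaded [load_study()] result (avoids re-reading).
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class `pudi_run`: `space` (selected features), `scores`
#'   (feature score table), `partition`, `model`, `predictions` (one row per
#'   unlabeled gene), `manifest`.
#' @export
run_pudi <- function(config, study = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pudi_config"))
  if (is.null(study)) study <- load_study(config)
  p <- study$positives
  u <- study$unlabeled
  candidate <- feature_space_from_study(study$records, study$dags)
  scores <- score_features(study$records, p, u, candidate, study$dags,
                           normalize = config$normalize_af)
  selected <- select_top_n(scores, config$n_top_features)
  x <- featurize_genes(study$records[c(p, u)], selected, study$dags,
                       study$net, known_positives = p)
  partition <- partition_genes(x, p, u, q_neighbors = config$q_neighbors,
                               alpha = config$alpha, epsilon = config$epsilon,
                               max_iter = config$max_iter)
  profile <- if (!is.null(config$penalty_grid))
    select_penalties(x, partition, config$penalty_grid,
                     folds = config$folds, seed = config$seed,
                     kernel = config$kernel)
  else config$profile
  model <- train_weighted_svm(x, partition, profile, kernel = config$kernel,
                              calibrate = config$calibrate,
                              seed = config$seed)
  predictions <- stats::predict(model, x[u, , drop = FALSE])
  manifest <- list(package = "pudi",
                   version = as.character(utils::packageVersion("pudi")),
                   seed = config$seed,
                   parameters = list(n_top_features = config$n_top_features,
                                     q_neighbors = config$q_neighbors,
                                     alpha = config$alpha,
                                     epsilon = config$epsilon,
                                     kernel = config$kernel,
                                     balance = config$balance),
                   n_positive = length(p), n_unlabeled = length(u))
  run <- structure(list(space = selected, scores = scores,
                        partition = partition, model = model,
                        features = x, predictions = predictions,
                        manifest = manifest),
                   class = "pudi_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_scores(scores, selected, file.path(out_dir, "feature_scores.tsv"))
    write_partition(partition, file.path(out_dir, "partition.tsv"))
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pudi_model(model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.pudi_run <- function(x, ...) {
  cat("pudi_run over", x$manifest$n_positive, "positives and",
      x$manifest$n_unlabeled, "unlabeled genes\n")
  print(x$partition)
  cat(sum(x$predictions$label == "disease"),
      "unlabeled genes predicted as disease genes\n")
  invisible(x)
}

#' k-fold cross-validated evaluation
#'
#' Stratified folds over P and U. Within each fold, feature selection, the
#' PPI disease-neighborhood features, PPI scaling ranges, the partition and
#' the classifier are all computed from the training genes only; the held-out
#' genes are then scored with P-membership as the ground truth. Precision,
#' recall and F-measure are averaged over folds; the ROC is computed from the
#' pooled held-out probabilities.
#'
#' @param config a [pudi_config()].
#' @param study optional preloaded [load_study()] result.
#' @param k folds (default `config$folds`).
#' @return list of class `pudi_metrics`: `precision`, `recall`, `f_measure`,
#'   `auc` (proportions in \[0,1\]), `per_fold` data.frame and `roc` points.
#' @export
kfold_evaluate <- function(config, study = NULL, k = config$folds) {
  stopifnot(k >= 2)
  if (is.null(study)) study <- load_study(config)
  p <- study$positives
  u <- study$unlabeled
  k <- min(k, length(p), length(u))
  fold_p <- .seeded_folds(length(p), k, config$seed)
  fold_u <- .seeded_folds(length(u), k, config$seed + 1L)
  candidate <- feature_space_from_study(study$records, study$dags)
  per_fold <- list()
  pooled <- data.frame()
  for (f in seq_len(k)) {
    test_p <- p[fold_p == f]; test_u <- u[fold_u == f]
    train_p <- setdiff(p, test_p); train_u <- setdiff(u, test_u)
    if (!length(test_p)) {
      warning("fold ", f, " has no held-out positives; skipped")
      next
    }
    # leakage guard: everything label-dependent sees training positives only
    known_positives <- train_p
    stopifnot(!any(known_positives %in% test_p))
    scores <- score_features(study$records, train_p, train_u, candidate,
                             study$dags, normalize = config$normalize_af)
    selected <- select_top_n(scores, config$n_top_features)
    x_train <- featurize_genes(study$records[c(train_p, train_u)], selected,
                               study$dags, study$net,
                               known_positives = known_positives)
    partition <- partition_genes(x_train, train_p, train_u,
                                 q_neighbors = config$q_neighbors,
                                 alpha = config$alpha,
                                 epsilon = config$epsilon,
                                 max_iter = config$max_iter)
    profile <- if (!is.null(config$penalty_grid))
      select_penalties(x_train, partition, config$penalty_grid,
                       folds = config$folds, seed = config$seed,
                       kernel = config$kernel)
    else config$profile
    model <- train_weighted_svm(x_train, partition, profile,
                                kernel = config$kernel,
                                calibrate = config$calibrate,
                                seed = config$seed)
    x_test <- featurize_genes(study$records[c(test_p, test_u)], selected,
                              study$dags, study$net,
                              known_positives = known_positives,
                              ppi_ranges = attr(x_train, "ppi_ranges"))
    pred <- stats::predict(model, x_test)
    truth <- pred$gene_id %in% test_p
    m <- .prf(truth, pred$label == "disease")
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, precision = m["precision"], recall = m["recall"],
                 f_measure = m["f_measure"], row.names = NULL)
    pooled <- rbind(pooled, data.frame(truth = truth,
                                       probability = pred$probability))
  }
  if (!length(per_fold)) stop("no evaluable folds")
  per_fold <- do.call(rbind, per_fold)
  structure(list(precision = mean(per_fold$precision),
                 recall = mean(per_fold$recall),
                 f_measure = mean(per_fold$f_measure),
                 auc = .auc(pooled$truth, pooled$probability),
                 per_fold = per_fold,
                 roc = .roc_points(pooled$truth, pooled$probability)),
            class = "pudi_metrics")
}

#' @export
print.pudi_metrics <- function(x, ...) {
  cat(sprintf("precision %.1f%%  recall %.1f%%  F-measure %.1f%%  AUC %.3f\n",
              100 * x$precision, 100 * x$recall, 100 * x$f_measure, x$auc))
  invisible(x)
}

#' Hidden-positive recovery on a synthetic study
#'
#' Runs the pipeline on a generated study and measures how well the hidden
#' positives planted inside the unlabeled set are recovered: AUC of the
#' decision scores over U (hidden positives vs true negatives) and the
#' F-measure of the predicted disease labels against the truth list. The
#' naive P-vs-U SVM control is evaluated on the same feature matrix.
#'
#' @param study a [generate_synthetic_study()] result.
#' @param config a [pudi_config()]; input paths are taken from the study.
#' @return list with `auc`, `precision`, `recall`, `f_measure`,
#'   `baseline_auc`, `baseline_f`, and the `run`.
#' @export
hidden_positive_recovery <- function(study,
                                     config = pudi_config(calibrate = FALSE)) {
  stopifnot(inherits(study, "pudi_study"))
  config[c("obo", "annotations", "domains", "ppi", "positives", "unlabeled")] <-
    study$paths[c("obo", "annotations", "domains", "ppi", "positives",
                  "unlabeled")]
  class(config) <- "pudi_config"
  run <- run_pudi(config)
  pred <- run$predictions
  truth <- pred$gene_id %in% study$hidden_positives
  m <- .prf(truth, pred$label == "disease")
  base <- naive_svm_baseline(run$features, study$positives, study$unlabeled)
  bscores <- base(run$features[study$unlabeled, , drop = FALSE])
  bm <- .prf(truth, bscores > 0)
  list(auc = .auc(truth, pred$score),
       precision = unname(m["precision"]), recall = unname(m["recall"]),
       f_measure = unname(m["f_measure"]),
       baseline_auc = .auc(truth, bscores),
       baseline_f = unname(bm["f_measure"]),
       run = run)
}
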