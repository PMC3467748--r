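plain_partition <- function(pos, neg) {
  list(p = pos, rn = neg, lp = character(0), ln = character(0),
       wn = character(0))
}

test_that("penalty profile enforces the trust orderings", {
  prof <- penalty_profile()
  expect_gt(prof$c_p, prof$c_lp)
  expect_true(prof$c_rn > prof$c_ln && prof$c_ln > prof$c_wn)
  expect_error(penalty_profile(c_p = 0.5, c_lp = 0.5), "c_p > c_lp")
  expect_error(penalty_profile(c_ln = 0.1, c_wn = 0.2), "c_rn > c_ln > c_wn")
  expect_error(penalty_profile(c_p = -1), "positive")
})

test_that("collapsed-penalty training equals a plain two-class soft-margin SVM", {
  toy <- separable_toy(n = 60, gap = 1.0)
  part <- plain_partition(toy$pos, toy$neg)
  prof <- penalty_profile(c_p = 1, c_lp = 0.5, c_rn = 1, c_ln = 0.5,
                          c_wn = 0.25)  # only c_p/c_rn = 1 are in play
  m <- train_weighted_svm(toy$x, part, prof, calibrate = FALSE)
  mine <- decision_values(m, toy$x)
  ref <- e1071::svm(toy$x, factor(c(rep("pos", 30), rep("neg", 30)),
                                  levels = c("neg", "pos")),
                    kernel = "linear", cost = 1, scale = FALSE)
  dv <- as.numeric(attr(predict(ref, toy$x, decision.values = TRUE),
                        "decision.values"))
  if (stats::cor(dv, mine) < 0) dv <- -dv
  expect_lt(max(abs(mine - dv)), 0.02)
  expect_identical(unname(sign(mine)[abs(mine) > 0.05]),
                   sign(dv)[abs(dv) > 0.05])
})

test_that("a separable toy with large penalties is fit without training errors", {
  toy <- separable_toy(n = 40, gap = 2.5)
  prof <- penalty_profile(c_p = 100, c_lp = 50, c_rn = 100, c_ln = 50,
                          c_wn = 25)
  m <- train_weighted_svm(toy$x, plain_partition(toy$pos, toy$neg), prof,
                          calibrate = FALSE)
  d <- decision_values(m, toy$x)
  expect_true(all(d[toy$pos] > 0))
  expect_true(all(d[toy$neg] < 0))
})

test_that("a near-zero-penalty WN point cannot move the boundary", {
  toy <- separable_toy(n = 40, gap = 2)
  intruder <- matrix(c(2, 2), 1, dimnames = list("wn1", colnames(toy$x)))
  x2 <- rbind(toy$x, intruder)  # WN point deep inside the positive side
  prof <- penalty_profile(c_p = 1, c_lp = 0.5, c_rn = 1, c_ln = 0.5,
                          c_wn = 1e-6)
  m_with <- train_weighted_svm(
    x2, list(p = toy$pos, rn = toy$neg, lp = character(0),
             ln = character(0), wn = "wn1"), prof, calibrate = FALSE)
  m_without <- train_weighted_svm(toy$x, plain_partition(toy$pos, toy$neg),
                                  prof, calibrate = FALSE)
  expect_lt(max(abs(decision_values(m_with, toy$x) -
                    decision_values(m_without, toy$x))), 1e-3)
})

test_that("raising C_P does not increase misclassified positives on a noisy toy", {
  set.seed(41)
  x <- rbind(matrix(stats::rnorm(60, mean = 0.7), ncol = 2),
             matrix(stats::rnorm(60, mean = -0.7), ncol = 2))
  rownames(x) <- sprintf("g%02d", 1:60)
  part <- plain_partition(rownames(x)[1:30], rownames(x)[31:60])
  errs <- vapply(c(0.6, 1, 2, 4, 8), function(cp) {
    prof <- penalty_profile(c_p = cp, c_lp = 0.5, c_rn = 1, c_ln = 0.5,
                            c_wn = 0.25)
    m <- train_weighted_svm(x, part, prof, calibrate = FALSE)
    sum(decision_values(m, x[part$p, ]) <= 0)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("predictions carry the sign rule, monotone probabilities, tie to non-disease", {
  toy <- separable_toy(n = 40, gap = 2)
  m <- train_weighted_svm(toy$x, plain_partition(toy$pos, toy$neg),
                          penalty_profile(), calibrate = TRUE, seed = 3)
  pred <- predict(m, toy$x)
  expect_true(all(pred$label[pred$gene_id %in% toy$pos] == "disease"))
  ord <- order(pred$score)
  expect_true(all(diff(pred$probability[ord]) >= 0))
  expect_identical(pred$label[pred$score <= 0] == "disease",
                   rep(FALSE, sum(pred$score <= 0)))
  # a score of exactly zero is non-disease
  null_model <- m
  null_model$alpha <- rep(0, length(m$alpha))
  null_model$b <- 0
  p0 <- predict(null_model, toy$x)
  expect_true(all(p0$score == 0))
  expect_true(all(p0$label == "non-disease"))
  expect_error(decision_values(m, matrix(0, 2, 3)), "mismatch")
})

test_that("calibration probabilities separate positives from reliable negatives", {
  toy <- separable_toy(n = 60, gap = 1.2)
  m <- train_weighted_svm(toy$x, plain_partition(toy$pos, toy$neg),
                          penalty_profile(), calibrate = TRUE, seed = 5)
  pred <- predict(m, toy$x)
  expect_gt(mean(pred$probability[pred$gene_id %in% toy$pos]),
            mean(pred$probability[pred$gene_id %in% toy$neg]))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
})

test_that("penalty search filters infeasible rows and is reproducible", {
  toy <- separable_toy(n = 40, gap = 1)
  part <- plain_partition(toy$pos, toy$neg)
  single <- data.frame(c_p = 2, c_lp = 1, c_rn = 1, c_ln = 0.5, c_wn = 0.25)
  prof <- select_penalties(toy$x, part, single, folds = 3, seed = 1)
  expect_equal(prof$c_p, 2)
  grid <- rbind(single,
                data.frame(c_p = 1, c_lp = 2, c_rn = 1, c_ln = 0.5,
                           c_wn = 0.25))  # violates c_p > c_lp
  expect_message(prof2 <- select_penalties(toy$x, part, grid, folds = 3,
                                           seed = 1), "filtered")
  expect_equal(nrow(attr(prof2, "search")), 1)
  g2 <- default_penalty_grid()
  expect_true(all(g2$c_p > g2$c_lp & g2$c_rn > g2$c_ln & g2$c_ln > g2$c_wn))
  a <- select_penalties(toy$x, part, g2[1:4, ], folds = 3, seed = 7)
  b <- select_penalties(toy$x, part, g2[1:4, ], folds = 3, seed = 7)
  expect_identical(unclass(a)[1:5], unclass(b)[1:5])
})

test_that("model serialization round-trips", {
  toy <- separable_toy(n = 20, gap = 2)
  m <- train_weighted_svm(toy$x, plain_partition(toy$pos, toy$neg),
                          penalty_profile(), calibrate = FALSE)
  f <- tempfile(fileext = ".rds")
  write_pudi_model(m, f)
  m2 <- read_pudi_model(f)
  expect_identical(decision_values(m2, toy$x), decision_values(m, toy$x))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(read_pudi_model(bad), "not a pudi model")
})

test_that("the naive baseline orients scores toward the positive class", {
  toy <- separable_toy(n = 40, gap = 1.5)
  scorer <- naive_svm_baseline(toy$x, toy$pos, toy$neg)
  s <- scorer(toy$x)
  expect_gt(mean(s[toy$pos]), mean(s[toy$neg]))
})
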