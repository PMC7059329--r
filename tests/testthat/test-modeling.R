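ALL_METHODS <- c("nb", "knn_weighted", "rlr", "svm_rbf", "sgb", "xgboost",
                 "dnn")

test_that("specs validate methods, hyperparameters and DNN fixed settings", {
  expect_error(classifier_spec("random_guess"), "unknown method")
  expect_error(classifier_spec("svm_rbf", list(k = 3)),
               "unknown hyperparameter")
  expect_error(classifier_spec("dnn", list(epochs = 500L)), "cap is 300")
  s <- classifier_spec("svm_rbf", list(cost = 2))
  expect_equal(s$hyperparameters$cost, 2)
  expect_equal(s$hyperparameters$gamma, 0.1)  # registry default retained
})

test_that("every method separates a linearly separable set perfectly", {
  set.seed(1)
  n <- 60
  x <- cbind(f1 = c(rnorm(n, 3), rnorm(n, -3)),
             f2 = c(rnorm(n, 3), rnorm(n, -3)))
  y <- rep(c(1L, 0L), each = n)
  for (m in ALL_METHODS) {
    spec <- classifier_spec(m, seed = 2)
    model <- train_classifier(spec, x, y)
    p <- predict_prob(model, x)
    expect_true(all(p >= 0 & p <= 1), info = m)
    expect_equal(mean(as.integer(p >= 0.5) == y), 1, info = m)
  }
  expect_error(train_classifier(classifier_spec("nb"), x, rep(1L, 2 * n)),
               "single-class")
})

test_that("1-nearest-neighbour memorizes its training data", {
  ft <- make_sep_table(30, 30, d = 1, seed = 4)
  model <- train_classifier(classifier_spec("knn_weighted", list(k = 1L)),
                            ft$x, ft$labels)
  p <- predict_prob(model, ft$x)
  expect_equal(as.integer(p >= 0.5), ft$labels)
})

test_that("label-permuted data drives cross-validated MCC to zero", {
  set.seed(10)
  ft <- make_sep_table(120, 120, d = 2, seed = 10)
  y_perm <- sample(ft$labels)
  folds <- random_kfold(y_perm, k = 5, seed = 11)
  for (m in c("rlr", "xgboost")) {
    cv <- cross_validate(classifier_spec(m, seed = 12), ft$x, y_perm, folds)
    expect_lt(abs(cv$metrics$MCC), 0.15, label = paste(m, "permuted MCC"))
  }
})

test_that("stochastic methods are reproducible under a fixed seed", {
  ft <- make_sep_table(40, 40, d = 1, seed = 20)
  for (m in c("sgb", "xgboost", "dnn")) {
    m1 <- train_classifier(classifier_spec(m, seed = 5), ft$x, ft$labels)
    m2 <- train_classifier(classifier_spec(m, seed = 5), ft$x, ft$labels)
    expect_identical(predict_prob(m1, ft$x), predict_prob(m2, ft$x),
                     info = m)
  }
})

test_that("prediction sets pair probabilities with >= 0.5 labels", {
  ps <- prediction_set(c("a", "b", "c"), c(0.49, 0.5, 0.9))
  expect_equal(ps$predicted_label, c(0L, 1L, 1L))
  expect_error(prediction_set("a", 1.4), "\\[0,1\\]")
})

test_that("consensus voting follows majority and mean-probability rules", {
  ids <- c("a", "b", "c")
  p1 <- prediction_set(ids, c(0.9, 0.1, 0.2))
  p2 <- prediction_set(ids, c(0.8, 0.2, 0.3))
  p3 <- prediction_set(ids, c(0.1, 0.3, 0.9))
  cl <- consensus_label(list(p1, p2, p3))
  expect_equal(cl$predicted_label, c(1L, 0L, 0L))
  expect_equal(cl$p_inhibitor, c(2 / 3, 0, 1 / 3))
  expect_error(consensus_label(list(p1, p2)), "odd number")
  # identical members reproduce any member
  expect_equal(consensus_label(list(p1, p1, p1))$predicted_label,
               p1$predicted_label)
  cp <- consensus_probability(list(p1, p2, p3))
  expect_equal(cp$p_inhibitor, c(0.6, 0.2, 7 / 15))
  # boundary: mean exactly 0.5 classifies as inhibitor
  q1 <- prediction_set(ids[1], 0.4)
  q2 <- prediction_set(ids[1], 0.6)
  expect_equal(consensus_probability(list(q1, q2))$predicted_label, 1L)
  # single member is the identity
  expect_equal(consensus_probability(list(p1))$p_inhibitor, p1$p_inhibitor)
  expect_error(consensus_label(list(p1, prediction_set(c("x", "y", "z"),
                                                       c(0.1, 0.2, 0.3)))),
               "not aligned")
})

test_that("hyper-parameter tuning finds the constructed k-NN optimum", {
  # high-noise data where very small k overfits: tuning should not pick k=1
  ft <- gen_feature_table(synthetic_spec(
    n_inhibitors = 120, n_noninhibitors = 120,
    n_informative_continuous = 2, n_noise_continuous = 8,
    n_fingerprint_bits = 0, effect_size = 0.9, seed = 30))
  grid <- list(k = c(1L, 3L, 5L, 7L, 9L))
  res <- tune_hyperparameters("knn_weighted", ft$x, ft$labels, grid = grid,
                              n_refine = 0L, seed = 31)
  # exhaustive oracle over the same grid and folds (per-fold mean MCC,
  # the tuning objective)
  folds <- random_kfold(ft$labels, k = 5, seed = 31)
  oracle <- vapply(grid$k, function(k) {
    spec <- classifier_spec("knn_weighted", list(k = k), seed = 31)
    mean(vapply(1:5, function(f) {
      m <- train_classifier(spec, ft$x[folds != f, , drop = FALSE],
                            ft$labels[folds != f])
      p <- predict_prob(m, ft$x[folds == f, , drop = FALSE])
      cm <- confusion(ft$labels[folds == f], as.integer(p >= 0.5))
      mcc(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$spec$hyperparameters$k, grid$k[which.max(oracle)])
  expect_equal(res$best_mcc, max(oracle))
})

test_that("tuning degenerates gracefully and reproducibly", {
  ft <- make_sep_table(40, 40, d = 2, seed = 33)
  one <- tune_hyperparameters("rlr", ft$x, ft$labels,
                              grid = list(alpha = 0, lambda = 0.01),
                              n_refine = 0L, seed = 2)
  expect_equal(one$spec$hyperparameters$lambda, 0.01)
  expect_error(tune_hyperparameters("rlr", ft$x, ft$labels,
                                    grid = list(), seed = 2),
               "empty search space")
  a <- tune_hyperparameters("xgboost", ft$x, ft$labels,
                            grid = list(nrounds = c(10L, 20L),
                                        max_depth = c(2L, 3L)),
                            n_refine = 2L, seed = 3)
  b <- tune_hyperparameters("xgboost", ft$x, ft$labels,
                            grid = list(nrounds = c(10L, 20L),
                                        max_depth = c(2L, 3L)),
                            n_refine = 2L, seed = 3)
  expect_identical(a$log, b$log)
  expect_true(all(c("grid", "refine") %in% a$log$stage))
})
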