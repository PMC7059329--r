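test_that("confusion counts match explicit enumeration", {
  truth <- c(rep(1L, 10), rep(0L, 10))
  expect_equal(confusion(truth, truth),
               c(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  expect_equal(confusion(truth, rep(1L, 20)),
               c(TP = 10L, TN = 0L, FP = 10L, FN = 0L))
  set.seed(42)
  pred <- sample(0:1, 20, replace = TRUE)
  cm <- confusion(truth, pred)
  # brute-force count
  expect_equal(unname(cm["TP"]), sum(truth == 1 & pred == 1))
  expect_equal(unname(cm["FN"]), sum(truth == 1 & pred == 0))
  expect_equal(unname(cm["FP"]), sum(truth == 0 & pred == 1))
  expect_equal(sum(cm), 20L)
  expect_error(confusion(truth, pred[-1]), "length")
})

test_that("GA, BA and MCC follow their formulas exactly", {
  expect_equal(global_accuracy(50, 90, 10, 50), 0.70)
  expect_equal(balanced_accuracy(50, 90, 10, 50), 0.5 * (0.5 + 0.9))
  expect_equal(mcc(10, 10, 0, 0), 1.0)
  expect_equal(mcc(10, 0, 10, 0), 0)   # zero-denominator convention
  expect_equal(mcc(200, 320, 20, 19), mcc_oracle(200, 320, 20, 19))
  expect_error(balanced_accuracy(0, 10, 5, 0), "undefined")
})

test_that("metrics agree with the arithmetic oracle over small matrices", {
  grid <- expand.grid(tp = 0:8, tn = 0:8, fp = 0:8, fn = 0:8)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(mcc(g$tp, g$tn, g$fp, g$fn),
                     mcc_oracle(g$tp, g$tn, g$fp, g$fn))
    if (g$tp + g$tn + g$fp + g$fn > 0) {
      expect_identical(global_accuracy(g$tp, g$tn, g$fp, g$fn),
                       (g$tp + g$tn) / sum(g))
    }
    if (g$tp + g$fn > 0 && g$tn + g$fp > 0) {
      expect_identical(balanced_accuracy(g$tp, g$tn, g$fp, g$fn),
                       0.5 * (g$tp / (g$tp + g$fn) + g$tn / (g$tn + g$fp)))
    }
  }
})

test_that("MCC and BA are invariant under simultaneous class flip", {
  set.seed(7)
  for (i in 1:20) {
    cm <- sample(0:15, 4, replace = TRUE)
    # flip: TP<->TN, FP<->FN
    expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]),
                 mcc(cm[2], cm[1], cm[4], cm[3]))
    if (cm[1] + cm[4] > 0 && cm[2] + cm[3] > 0) {
      expect_equal(balanced_accuracy(cm[1], cm[2], cm[3], cm[4]),
                   balanced_accuracy(cm[2], cm[1], cm[4], cm[3]))
    }
  }
})

test_that("cross-entropy residual has the closed-form values", {
  expect_equal(cross_entropy_residual(1L, 1), 0, tolerance = 1e-12)
  expect_equal(cross_entropy_residual(1L, 0.5), log(2))
  # a confident correct prediction beats a hesitant one
  expect_lt(cross_entropy_residual(1L, 0.9), cross_entropy_residual(1L, 0.6))
  expect_error(cross_entropy_residual(1L, 1.2), "\\[0, 1\\]")
  # clipping keeps wrong-and-confident finite
  expect_true(is.finite(cross_entropy_residual(1L, 0)))
})

test_that("residual exceedance curve equals 1 - ECDF and is monotone", {
  expect_equal(residual_distribution(c(0, 0, 0), c(0.1, 1))$exceedance,
               c(0, 0))
  expect_equal(residual_distribution(c(0.2, 0.8), 0.5)$exceedance, 0.5)
  set.seed(3)
  r <- rexp(200)
  grid <- seq(0, 4, by = 0.1)
  curve <- residual_distribution(r, grid)$exceedance
  ecdf_based <- 1 - ecdf(r)(grid)
  expect_equal(curve, ecdf_based)
  expect_true(all(diff(curve) <= 0))
  expect_error(residual_distribution(numeric(0)), "empty")
})

test_that("AUC matches the pair-counting oracle, ties by midrank", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.7, 0.7, 0.3, 0.7, 0.5, 0.3, 0.3, 0.2, 0.1)
  expect_equal(auc_score(y, p), auc_oracle(y, p))
  set.seed(11)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(30), 1)  # force ties
    expect_equal(auc_score(y, p), auc_oracle(y, p))
  }
  expect_error(auc_score(rep(1L, 5), runif(5)), "both classes")
})

test_that("random AUC is near one half on class-independent scores", {
  set.seed(5)
  y <- rep(c(0L, 1L), each = 1000)
  expect_lt(abs(auc_score(y, runif(2000)) - 0.5), 0.05)
})

test_that("tanimoto similarity counts bit overlap", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  # bits {1,2,3} vs {2,3,4} -> 2/4
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)  # empty convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("random stratified folds partition the data evenly", {
  y <- rep(c(0L, 1L), each = 50)
  f <- random_kfold(y, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 10)
    expect_equal(sum(f == k & y == 0), 10)
  }
  expect_identical(f, random_kfold(y, k = 5, seed = 3))
  expect_false(identical(f, random_kfold(y, k = 5, seed = 4)))
  expect_error(random_kfold(y, k = 1), "at least 2")
})

test_that("cluster folds keep complete-linkage clusters intact", {
  set.seed(9)
  # 6 scaffold families: near-identical bit patterns within a family
  proto <- matrix(rbinom(6 * 64, 1, 0.3), 6, 64)
  bits <- proto[rep(1:6, each = 5), ]
  flip <- matrix(runif(30 * 64) < 0.01, 30, 64)
  bits <- abs(bits - flip * 1)
  cf <- cluster_folds(bits, k = 5, distance_threshold = 0.7, seed = 2)
  expect_equal(length(cf$fold), 30)
  # all members of a cluster share a fold
  for (cl in unique(cf$cluster)) {
    expect_equal(length(unique(cf$fold[cf$cluster == cl])), 1L)
  }
  # complete-linkage contract: intra-cluster distance <= cut, by pair scan
  d <- 1 - bcrpqsar:::.tanimoto_matrix(bits)
  for (cl in unique(cf$cluster)) {
    ix <- which(cf$cluster == cl)
    if (length(ix) > 1) expect_lte(max(d[ix, ix]), 0.7)
  }
  # identical compounds cluster (and fold) together
  bits2 <- rbind(bits, bits[1, ])
  cf2 <- cluster_folds(bits2, k = 5, seed = 2)
  expect_equal(cf2$fold[31], cf2$fold[1])
})

test_that("mutually dissimilar compounds give balanced singleton folds", {
  bits <- diag(1, 12)  # pairwise Tanimoto 0
  cf <- cluster_folds(bits, k = 5, distance_threshold = 0.7, seed = 1)
  expect_equal(cf$n_clusters, 12)
  expect_lte(diff(range(cf$fold_sizes)), 1)
  expect_error(cluster_folds(bits[1:3, ], k = 5), "at least k")
})
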