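#' Confusion counts for binary predictions
#'
#' Tabulates true/false positives and negatives with the inhibitor class
#' (label 1) as the positive class.
#'
#' @param truth integer vector of observed labels (0/1).
#' @param predicted integer vector of predicted labels (0/1), same length.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length")
  }
  .check_binary(truth)
  .check_binary(predicted)
  c(TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L))
}

.check_binary <- function(x) {
  if (anyNA(x) || !all(x %in% c(0L, 1L))) stop("labels must be 0/1 without NA")
  invisible(TRUE)
}

#' Global accuracy
#'
#' `GA = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @return accuracy in \[0, 1\].
#' @export
global_accuracy <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  if (n <= 0) stop("no predictions to evaluate")
  (TP + TN) / n
}

#' Balanced accuracy
#'
#' `BA = 0.5 * (TP / (TP + FN) + TN / (TN + FP))`, the mean of sensitivity
#' and specificity. Errors if either class is absent.
#'
#' @inheritParams global_accuracy
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(TP, TN, FP, FN) {
  if (TP + FN == 0 || TN + FP == 0) {
    stop("balanced accuracy undefined: one class has no members")
  }
  0.5 * (TP / (TP + FN) + TN / (TN + FP))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(FN+TN)(TN+FP))`. When any
#' factor of the denominator is zero the coefficient is undefined; the
#' conventional value 0 (no correlation) is returned.
#'
#' @inheritParams global_accuracy
#' @return value in \[-1, 1\].
#' @export
mcc <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  den2 <- (TP + FN) * (TP + FP) * (FN + TN) * (TN + FP)
  if (den2 == 0) return(0)
  # products can overflow integer range; promote to double first
  (as.numeric(TP) * TN - as.numeric(FN) * FP) / sqrt(den2)
}

#' Binary cross-entropy residual
#'
#' Per-compound probabilistic residual `-[y*ln(p) + (1-y)*ln(1-p)]` with the
#' natural logarithm. Probabilities are clipped to `[eps, 1 - eps]` before
#' taking logs so that confident but wrong predictions stay finite.
#'
#' @param y observed labels (0/1).
#' @param p predicted inhibitor probabilities in \[0, 1\].
#' @param eps clipping constant, default `1e-15`.
#' @return non-negative residual vector.
#' @export
cross_entropy_residual <- function(y, p, eps = 1e-15) {
  .check_binary(y)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Residual exceedance profile
#'
#' Empirical curve of the fraction of compounds whose cross-entropy residual
#' exceeds each threshold of a grid (the residual-distribution diagnostic for
#' comparing models that share a confusion matrix).
#'
#' @param residuals non-negative finite residuals.
#' @param grid increasing threshold grid; default 100 points spanning the
#'   residual range.
#' @return data.frame with columns `threshold` and `exceedance`.
#' @export
residual_distribution <- function(residuals, grid = NULL) {
  if (length(residuals) == 0L) stop("empty residual set")
  if (any(!is.finite(residuals))) stop("residuals must be finite")
  if (is.null(grid)) grid <- seq(0, max(residuals), length.out = 100L)
  exceed <- vapply(grid, function(t) mean(residuals > t), numeric(1))
  data.frame(threshold = grid, exceedance = exceed)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a randomly chosen inhibitor scores higher than a randomly chosen
#' non-inhibitor, counting ties as one half.
#'
#' @param truth observed labels (0/1); both classes must be present.
#' @param prob predicted inhibitor probabilities (any monotone score works).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(truth, prob) {
  .check_binary(truth)
  if (length(truth) != length(prob)) stop("length mismatch")
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes must be present")
  r <- rank(prob, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize binary predictions with the standard metric set
#'
#' Convenience wrapper returning GA, BA, MCC and AUC for one prediction set.
#'
#' @param truth observed labels (0/1).
#' @param prob predicted inhibitor probabilities.
#' @param threshold classification threshold; `p >= threshold` predicts 1.
#' @return one-row data.frame with TP/TN/FP/FN and GA/BA/MCC/AUC.
#' @export
evaluate_predictions <- function(truth, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  cm <- confusion(truth, pred)
  data.frame(TP = cm[["TP"]], TN = cm[["TN"]], FP = cm[["FP"]], FN = cm[["FN"]],
             GA = global_accuracy(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]]),
             BA = balanced_accuracy(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]]),
             MCC = mcc(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]]),
             AUC = auc_score(truth, prob))
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|` on equal-length binary vectors. Two all-zero
#' vectors are defined to have similarity 1 (identical fingerprints).
#'
#' @param a,b binary vectors (0/1) of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors must have equal length")
  .check_binary(a)
  .check_binary(b)
  both <- sum(a == 1L & b == 1L)
  any_ <- sum(a == 1L | b == 1L)
  if (any_ == 0L) return(1)
  both / any_
}

# Pairwise Tanimoto similarity matrix over rows of a 0/1 matrix.
.tanimoto_matrix <- function(bits) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "double"
  common <- tcrossprod(bits)
  ones <- rowSums(bits)
  union <- outer(ones, ones, "+") - common
  sim <- ifelse(union == 0, 1, common / pmax(union, 1e-300))
  sim[union == 0] <- 1
  diag(sim) <- 1
  sim
}

#' Random stratified k-fold assignment
#'
#' Assigns compounds to `k` folds, stratified by class so fold sizes differ
#' by at most one within each class.
#'
#' @param labels observed labels (0/1).
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @param repeats number of independent repetitions.
#' @param stratified stratify folds by class (default TRUE).
#' @return integer matrix `n x repeats` of fold indices in `1..k`; a single
#'   repeat returns a plain integer vector.
#' @export
random_kfold <- function(labels, k = 5L, seed = 1L, repeats = 1L,
                         stratified = TRUE) {
  .check_binary(labels)
  if (k < 2L) stop("k must be at least 2")
  n <- length(labels)
  if (n < k) stop("need at least k compounds")
  out <- matrix(0L, nrow = n, ncol = repeats)
  set.seed(seed)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    if (stratified) {
      for (cls in c(0L, 1L)) {
        ix <- which(labels == cls)
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    out[, r] <- fold
  }
  if (repeats == 1L) out[, 1L] else out
}

#' Cluster-aware k-fold assignment from fingerprints
#'
#' Builds scaffold-respecting folds: compounds are clustered by complete-
#' linkage agglomerative clustering on Tanimoto distance (1 - similarity),
#' the dendrogram is cut at `distance_threshold`, and whole clusters are then
#' distributed across folds by randomized greedy size balancing (each cluster,
#' in shuffled order, goes to the currently smallest fold). All members of a
#' cluster share a fold, so cross-validation tests generalization to unseen
#' chemotypes.
#'
#' @param bits 0/1 fingerprint matrix (rows = compounds).
#' @param k number of folds (default 5).
#' @param distance_threshold dendrogram cut height (default 0.7).
#' @param seed integer RNG seed for the cluster shuffle.
#' @return list with `fold` (integer vector), `cluster` (integer vector),
#'   `n_clusters`, and `fold_sizes`.
#' @export
cluster_folds <- function(bits, k = 5L, distance_threshold = 0.7, seed = 1L) {
  bits <- as.matrix(bits)
  n <- nrow(bits)
  if (n < k) stop("need at least k compounds")
  sim <- .tanimoto_matrix(bits)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, h = distance_threshold)
  ncl <- max(cl)
  if (ncl < k) stop("fewer clusters (", ncl, ") than folds (", k, ")")
  set.seed(seed)
  order_cl <- sample(seq_len(ncl))
  sizes <- tabulate(cl, nbins = ncl)
  fold_of_cluster <- integer(ncl)
  fold_sizes <- integer(k)
  # largest-first within the shuffled stream keeps folds near-equal
  for (ci in order_cl) {
    target <- which.min(fold_sizes)
    fold_of_cluster[ci] <- target
    fold_sizes[target] <- fold_sizes[target] + sizes[ci]
  }
  list(fold = fold_of_cluster[cl], cluster = as.integer(cl),
       n_clusters = ncl, fold_sizes = fold_sizes)
}

#' Cross-validate a classifier specification
#'
#' Fits the model on each training fold and predicts the held-out fold,
#' returning out-of-fold probabilities and the pooled metric summary.
#'
#' @param spec a [classifier_spec()].
#' @param x numeric feature matrix.
#' @param y labels (0/1).
#' @param folds integer fold assignment of length `nrow(x)`.
#' @return list with `prob` (out-of-fold probabilities), `metrics` (one-row
#'   data.frame), and `residuals` (cross-entropy residuals).
#' @export
cross_validate <- function(spec, x, y, folds) {
  stopifnot(length(folds) == nrow(x), length(y) == nrow(x))
  prob <- rep(NA_real_, nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- train_classifier(spec, x[tr, , drop = FALSE], y[tr])
    prob[!tr] <- predict_prob(model, x[!tr, , drop = FALSE])
  }
  list(prob = prob,
       metrics = evaluate_predictions(y, prob),
       residuals = cross_entropy_residual(y, prob))
}
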