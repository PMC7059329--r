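# Perturbation-based, model-agnostic feature importance with the binary
# cross-entropy loss.

#' Permutation feature importance
#'
#' For each feature, the column is shuffled across rows (all other columns
#' fixed), the mean cross-entropy loss of the model on the perturbed data is
#' recomputed, and the importance is the loss difference
#' `perturbed - baseline`. The shuffle is repeated `n_repeats` times with
#' distinct permutations and results are averaged; a constant column is
#' unchanged by any permutation, so its importance is exactly zero.
#'
#' @param model a `bcrp_model` (anything accepted by [predict_prob()]).
#' @param x numeric feature matrix the model predicts on.
#' @param y observed 0/1 labels.
#' @param n_repeats permutation repetitions per feature (default 10).
#' @param seed integer seed; fixed seed reproduces the table.
#' @param features features to assess (default: all columns of `x`).
#' @return data.frame of class `importance_table`, one row per feature:
#'   `feature`, `importance` (mean perturbed loss - baseline),
#'   `importance_sd`, `perturbed_loss`, `rank` (1 = most important), sorted
#'   by decreasing importance; attribute `baseline_loss` carries the
#'   unperturbed mean loss.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10L, seed = 1L,
                                   features = colnames(x)) {
  x <- as.matrix(x)
  .check_binary(y)
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    stop("feature(s) absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  baseline <- mean(cross_entropy_residual(y, predict_prob(model, x)))
  set.seed(seed)
  n <- nrow(x)
  rows <- lapply(features, function(f) {
    losses <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, f] <- xp[sample.int(n), f]
      mean(cross_entropy_residual(y, predict_prob(model, xp)))
    }, numeric(1))
    data.frame(feature = f,
               importance = mean(losses) - baseline,
               importance_sd = stats::sd(losses),
               perturbed_loss = mean(losses),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "baseline_loss") <- baseline
  attr(out, "n_repeats") <- as.integer(n_repeats)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top-of-table view of an importance table
#'
#' @param table an `importance_table`.
#' @param top_n rows to keep (default 10).
#' @return the truncated table (baseline attribute preserved).
#' @export
top_importance <- function(table, top_n = 10L) {
  stopifnot(inherits(table, "importance_table"))
  out <- utils::head(table, top_n)
  attr(out, "baseline_loss") <- attr(table, "baseline_loss")
  out
}
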