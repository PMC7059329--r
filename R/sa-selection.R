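# rfSA: simulated-annealing wrapper feature selection scored by random-forest
# accuracy, with external (held-out) accuracy tracked across resamples.

#' Configuration of the SA feature search
#'
#' @param max_iterations SA chain length per resample (the reference setting
#'   is 1000; scale down for quick runs).
#' @param n_folds,n_repeats resampling scheme: `n_folds`-fold
#'   cross-validation with `n_repeats` repetitions (defaults 5 x 5); each
#'   resample runs one SA chain on its internal 4/5 and tracks accuracy on
#'   the held-out 1/5.
#' @param t0 initial temperature of the geometric cooling schedule
#'   `T_i = t0 * alpha^i` (default 0.10). `t0 = 0` gives greedy
#'   hill-climbing; `t0 = Inf` disables cooling (pure random walk).
#' @param alpha geometric cooling factor (default 0.99).
#' @param toggle_max neighbor move toggles 1..`toggle_max` features chosen
#'   uniformly (default 3); moves to the empty subset are rejected.
#' @param init_prob probability that a feature enters the initial random
#'   subset (default 0.2).
#' @param num_trees random-forest size used as the internal scorer
#'   (default 100).
#' @param seed integer seed; fixed seed gives an identical trace.
#' @return list of class `sa_config`.
#' @export
sa_config <- function(max_iterations = 1000L, n_folds = 5L, n_repeats = 5L,
                      t0 = 0.10, alpha = 0.99, toggle_max = 3L,
                      init_prob = 0.2, num_trees = 100L, seed = 1L) {
  stopifnot(max_iterations >= 1L, n_folds >= 2L, n_repeats >= 1L,
            t0 >= 0 || is.infinite(t0), alpha > 0, alpha <= 1,
            toggle_max >= 1L, init_prob > 0, init_prob <= 1, num_trees >= 1L)
  structure(list(max_iterations = as.integer(max_iterations),
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 t0 = t0, alpha = alpha,
                 toggle_max = as.integer(toggle_max),
                 init_prob = init_prob,
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "sa_config")
}

# OOB accuracy of a random forest on (x, y) restricted to `subset`.
.rf_internal_accuracy <- function(x, y, subset, num_trees, seed) {
  fit <- ranger::ranger(
    x = x[, subset, drop = FALSE], y = factor(y, levels = c(0, 1)),
    num.trees = num_trees, seed = seed, num.threads = 1L,
    classification = TRUE
  )
  1 - fit$prediction.error
}

# Accuracy on held-out rows of a forest trained on the internal rows.
.rf_external_accuracy <- function(x_in, y_in, x_out, y_out, subset,
                                  num_trees, seed) {
  fit <- ranger::ranger(
    x = x_in[, subset, drop = FALSE], y = factor(y_in, levels = c(0, 1)),
    num.trees = num_trees, seed = seed, num.threads = 1L,
    classification = TRUE
  )
  pred <- stats::predict(fit, data = x_out[, subset, drop = FALSE])$predictions
  mean(as.integer(as.character(pred)) == y_out)
}

# One SA chain. Returns list(trace = data.frame, subsets = list of incumbent
# subsets per iteration). `external` is a function(subset, seed) or NULL.
.sa_chain <- function(x, y, config, chain_seed, external = NULL,
                      store_subsets = TRUE) {
  p <- ncol(x)
  feats <- colnames(x)
  set.seed(chain_seed)
  subset <- which(stats::runif(p) < config$init_prob)
  if (length(subset) == 0L) subset <- sample.int(p, 1L)
  acc <- .rf_internal_accuracy(x, y, subset, config$num_trees, chain_seed)
  it_internal <- numeric(config$max_iterations)
  it_external <- numeric(config$max_iterations)
  it_size <- integer(config$max_iterations)
  subsets <- if (store_subsets) vector("list", config$max_iterations) else NULL
  for (i in seq_len(config$max_iterations)) {
    cand <- .toggle_move(subset, p, config$toggle_max)
    cand_acc <- .rf_internal_accuracy(x, y, cand, config$num_trees,
                                      chain_seed + i)
    delta <- acc - cand_acc  # > 0 means the candidate is worse
    accept <- if (delta <= 0) TRUE else {
      t_i <- if (is.infinite(config$t0)) Inf else config$t0 * config$alpha^i
      if (t_i <= 0) FALSE else stats::runif(1) < exp(-delta / t_i)
    }
    if (accept) {
      subset <- cand
      acc <- cand_acc
    }
    it_internal[i] <- acc
    it_size[i] <- length(subset)
    if (store_subsets) subsets[[i]] <- feats[subset]
    if (!is.null(external)) it_external[i] <- external(subset, chain_seed + i)
  }
  list(trace = data.frame(iteration = seq_len(config$max_iterations),
                          size = it_size,
                          internal_accuracy = it_internal,
                          external_accuracy = it_external),
       subsets = subsets)
}

# Neighbor move: toggle 1..toggle_max random features; never empty.
.toggle_move <- function(subset, p, toggle_max) {
  repeat {
    k <- sample.int(toggle_max, 1L)
    flip <- sample.int(p, k)
    cand <- sort(union(setdiff(subset, flip), setdiff(flip, subset)))
    if (length(cand) > 0L) return(cand)
  }
}

#' Simulated-annealing feature-subset search (rfSA)
#'
#' For each resample of a repeated k-fold scheme, runs one SA chain on the
#' internal portion: the neighbor move toggles a few features; a candidate
#' subset is always accepted when its internal random-forest accuracy
#' improves (or ties) and otherwise accepted with probability
#' `exp(-delta / T_i)` where `delta` is the accuracy drop and
#' `T_i = t0 * alpha^i` cools geometrically. Internal accuracy is the
#' out-of-bag accuracy of the forest on the internal rows; external accuracy
#' is measured on the held-out fold.
#'
#' @param fm a [feature_matrix()] with labels, or a numeric matrix (then
#'   `labels` must be given); features should already be filtered and
#'   normalized.
#' @param labels 0/1 labels (ignored when `fm` carries labels).
#' @param config an [sa_config()].
#' @return object of class `sa_trace`: list with `trace` (long data.frame:
#'   `resample`, `iteration`, `size`, `internal_accuracy`,
#'   `external_accuracy`), `mean_external` (per-iteration mean over
#'   resamples), `subsets` (incumbent subset per resample x iteration) and
#'   `config`.
#' @export
sa_search <- function(fm, labels = NULL, config = sa_config()) {
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    labels <- fm$labels
  } else x <- as.matrix(fm)
  if (is.null(labels)) stop("labels required")
  .check_binary(labels)
  if (ncol(x) == 0L) stop("empty feature space")
  folds <- random_kfold(labels, k = config$n_folds, seed = config$seed,
                        repeats = config$n_repeats)
  folds <- if (is.matrix(folds)) folds else matrix(folds, ncol = 1L)
  traces <- list()
  subsets <- list()
  res_id <- 0L
  for (r in seq_len(config$n_repeats)) {
    for (f in seq_len(config$n_folds)) {
      res_id <- res_id + 1L
      holdout <- folds[, r] == f
      x_in <- x[!holdout, , drop = FALSE]
      y_in <- labels[!holdout]
      x_out <- x[holdout, , drop = FALSE]
      y_out <- labels[holdout]
      ext <- function(subset, seed) {
        .rf_external_accuracy(x_in, y_in, x_out, y_out, subset,
                              config$num_trees, seed)
      }
      chain_seed <- config$seed + 1000L * res_id
      ch <- .sa_chain(x_in, y_in, config, chain_seed, external = ext)
      ch$trace$resample <- res_id
      traces[[res_id]] <- ch$trace
      subsets[[res_id]] <- ch$subsets
    }
  }
  trace <- do.call(rbind, traces)
  mean_ext <- tapply(trace$external_accuracy, trace$iteration, mean)
  structure(list(
    trace = trace[, c("resample", "iteration", "size",
                      "internal_accuracy", "external_accuracy")],
    mean_external = data.frame(iteration = as.integer(names(mean_ext)),
                               mean_external_accuracy = as.numeric(mean_ext)),
    subsets = subsets,
    config = config
  ), class = "sa_trace")
}

#' Pick the best SA iteration and derive the final subset
#'
#' The best iteration maximizes the mean external accuracy across resamples
#' (earliest iteration on ties). The final feature subset is then re-derived
#' deterministically by running a single SA chain on the full training set
#' up to that iteration under a seed stored in the configuration, mirroring
#' the consolidation step of resampled wrapper selection.
#'
#' @param trace an `sa_trace` from [sa_search()].
#' @param fm,labels the full training data the trace was computed from.
#' @return list with `iteration`, `mean_external_accuracy`, and `features`
#'   (character vector, the selected subset).
#' @export
select_best_iteration <- function(trace, fm, labels = NULL) {
  stopifnot(inherits(trace, "sa_trace"))
  me <- trace$mean_external
  if (nrow(me) == 0L) stop("empty trace")
  best <- me$iteration[which.max(me$mean_external_accuracy)]
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    labels <- fm$labels
  } else x <- as.matrix(fm)
  cfg <- trace$config
  cfg$max_iterations <- as.integer(best)
  final_seed <- cfg$seed + 999983L
  ch <- .sa_chain(x, labels, cfg, final_seed, external = NULL,
                  store_subsets = TRUE)
  list(iteration = as.integer(best),
       mean_external_accuracy = max(me$mean_external_accuracy),
       features = ch$subsets[[best]])
}
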