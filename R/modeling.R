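# Modeling: seven classification algorithms behind one interface, two-stage
# hyper-parameter tuning by cross-validated MCC, and the two consensus rules.
#
# Methods: nb (Gaussian naive Bayes), knn_weighted (distance-weighted k-NN),
# rlr (regularized logistic regression), svm_rbf (RBF-kernel SVM),
# sgb (stochastic gradient boosting), xgboost, dnn (feed-forward ReLU MLP).

.METHODS <- c("nb", "knn_weighted", "rlr", "svm_rbf", "sgb", "xgboost", "dnn")

# Registry of tunable hyper-parameters (with defaults) per method.
.HP_REGISTRY <- list(
  nb          = list(laplace = 0),
  knn_weighted = list(k = 5L),
  rlr         = list(alpha = 0, lambda = 0.01),
  svm_rbf     = list(cost = 1, gamma = 0.1),
  sgb         = list(nrounds = 100L, eta = 0.1, max_depth = 3L,
                     subsample = 0.5),
  xgboost     = list(nrounds = 100L, eta = 0.1, max_depth = 4L,
                     subsample = 1, colsample_bytree = 1, lambda = 1),
  dnn         = list(hidden = 32L, n_layers = 2L, epochs = 100L,
                     learning_rate = 0.01, batch_size = 32L)
)

#' Classifier specification
#'
#' @param method one of `"nb"`, `"knn_weighted"`, `"rlr"`, `"svm_rbf"`,
#'   `"sgb"`, `"xgboost"`, `"dnn"`.
#' @param hyperparameters named list; names are validated against the
#'   method's registry. The DNN honors fixed settings: ReLU activation, an
#'   adaptive-learning-rate (Adam-type) optimizer, and an epoch cap of 300.
#' @param seed integer seed for stochastic methods.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(method, hyperparameters = list(), seed = 1L) {
  if (length(method) != 1L || !(method %in% .METHODS)) {
    stop("unknown method: ", paste(method, collapse = ", "),
         " (available: ", paste(.METHODS, collapse = ", "), ")")
  }
  reg <- .HP_REGISTRY[[method]]
  bad <- setdiff(names(hyperparameters), names(reg))
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(bad, collapse = ", "))
  }
  hp <- utils::modifyList(reg, hyperparameters)
  if (method == "dnn" && hp$epochs > 300L) {
    stop("DNN epoch cap is 300")
  }
  structure(list(method = method, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier
#'
#' Fits the method named in the spec and returns a handle supporting
#' probability prediction via [predict_prob()]. Training is reproducible
#' under the spec's seed for stochastic methods.
#'
#' @param spec a [classifier_spec()].
#' @param x numeric feature matrix (restricted to the selected subset).
#' @param y 0/1 labels; both classes must be present.
#' @return object of class `bcrp_model`.
#' @export
train_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  .check_binary(y)
  if (length(unique(y)) < 2L) stop("degenerate single-class labels")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$method,
    nb = e1071::naiveBayes(x, factor(y, levels = c(0, 1)),
                           laplace = hp$laplace),
    knn_weighted = list(x = x, y = y, k = as.integer(hp$k)),
    rlr = glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                         alpha = hp$alpha, lambda = hp$lambda),
    svm_rbf = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                         cost = hp$cost, gamma = hp$gamma,
                         probability = TRUE),
    sgb = .fit_xgb(x, y, nrounds = hp$nrounds, eta = hp$eta,
                   max_depth = hp$max_depth, subsample = hp$subsample,
                   colsample_bytree = 1, lambda = 0, seed = spec$seed),
    xgboost = .fit_xgb(x, y, nrounds = hp$nrounds, eta = hp$eta,
                       max_depth = hp$max_depth, subsample = hp$subsample,
                       colsample_bytree = hp$colsample_bytree,
                       lambda = hp$lambda, seed = spec$seed),
    dnn = .fit_mlp(x, y, hidden = rep(as.integer(hp$hidden),
                                      as.integer(hp$n_layers)),
                   epochs = as.integer(hp$epochs),
                   lr = hp$learning_rate,
                   batch_size = as.integer(hp$batch_size),
                   seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "bcrp_model")
}

.fit_xgb <- function(x, y, nrounds, eta, max_depth, subsample,
                     colsample_bytree, lambda, seed) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_depth = max_depth, subsample = subsample,
                  colsample_bytree = colsample_bytree, lambda = lambda,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

#' Predict inhibitor probabilities
#'
#' @param model a `bcrp_model` from [train_classifier()].
#' @param x numeric matrix with the model's feature columns.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "bcrp_model"))
  x <- as.matrix(x)[, model$features, drop = FALSE]
  fit <- model$fit
  p <- switch(model$spec$method,
    nb = stats::predict(fit, x, type = "raw")[, "1"],
    knn_weighted = .predict_wknn(fit, x),
    rlr = as.numeric(stats::predict(fit, x, type = "response")),
    svm_rbf = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    sgb = stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    dnn = .predict_mlp(fit, x)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Build a prediction set
#'
#' Pairs probabilities with hard labels using the fixed 0.5 threshold
#' (`p >= 0.5` predicts inhibitor).
#'
#' @param compound_id identifiers.
#' @param p_inhibitor probabilities in \[0, 1\].
#' @return data.frame of class `prediction_set` with `compound_id`,
#'   `p_inhibitor`, `predicted_label`.
#' @export
prediction_set <- function(compound_id, p_inhibitor) {
  if (any(p_inhibitor < 0 | p_inhibitor > 1)) stop("probabilities in [0,1]")
  out <- data.frame(compound_id = compound_id, p_inhibitor = p_inhibitor,
                    predicted_label = as.integer(p_inhibitor >= 0.5),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

# Distance-weighted k-NN probability (inverse Euclidean distance voting).
.predict_wknn <- function(fit, x) {
  k <- min(fit$k, nrow(fit$x))
  apply(x, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    nn <- order(d)[seq_len(k)]
    w <- 1 / (d[nn] + 1e-8)
    sum(w * fit$y[nn]) / sum(w)
  })
}

# ---- minimal feed-forward MLP (ReLU hidden layers, sigmoid output, ----
# ---- Adam optimizer, binary cross-entropy loss)                    ----

.fit_mlp <- function(x, y, hidden, epochs, lr, batch_size, seed) {
  set.seed(seed)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                        sd = sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(xs); t_step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      xb <- xs[ix, , drop = FALSE]
      yb <- y[ix]
      # forward
      a <- vector("list", L + 1L)
      a[[1L]] <- xb
      for (l in seq_len(L)) {
        z <- a[[l]] %*% W[[l]] + matrix(b[[l]], nrow(xb), sizes[l + 1L],
                                        byrow = TRUE)
        a[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
      }
      # backward (BCE + sigmoid output gives delta = p - y)
      delta <- (a[[L + 1L]] - yb) / length(ix)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_step)
        vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step)
        vhb <- vb[[l]] / (1 - beta2^t_step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  list(W = W, b = b, mu = mu, sd = sd_, sizes = sizes)
}

.predict_mlp <- function(fit, x) {
  xs <- sweep(sweep(as.matrix(x), 2, fit$mu), 2, fit$sd, "/")
  a <- xs
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- a %*% fit$W[[l]] + matrix(fit$b[[l]], nrow(a),
                                   ncol(fit$W[[l]]), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}

#' Tune hyper-parameters by cross-validated MCC
#'
#' Two-stage search: a coarse grid over `grid` is evaluated by mean k-fold
#' CV MCC under fixed folds; the search then zooms into the region spanned
#' by the best-scoring grid points (top quartile) and samples `n_refine`
#' random configurations inside it (sequential refinement with a random
#' surrogate). Returns the best specification and the full search log.
#'
#' @param method classifier method name.
#' @param x,y training data.
#' @param grid named list of parameter value vectors defining the coarse
#'   grid (defaults to a small built-in grid per method).
#' @param n_refine number of refinement samples (default 10; 0 disables the
#'   second stage).
#' @param k CV folds (default 5).
#' @param seed integer seed fixing folds and sampling.
#' @return list with `spec` (best [classifier_spec()]), `best_mcc`, and
#'   `log` (data.frame of every evaluated configuration).
#' @export
tune_hyperparameters <- function(method, x, y, grid = NULL, n_refine = 10L,
                                 k = 5L, seed = 1L) {
  if (is.null(grid)) grid <- .default_grid(method)
  if (length(grid) == 0L || any(!lengths(grid))) stop("empty search space")
  bad <- setdiff(names(grid), names(.HP_REGISTRY[[method]]))
  if (length(bad)) stop("unknown hyperparameter(s): ",
                        paste(bad, collapse = ", "))
  folds <- random_kfold(y, k = k, seed = seed)
  score <- function(hp) {
    spec <- classifier_spec(method, hp, seed = seed)
    mean(vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      m <- train_classifier(spec, x[tr, , drop = FALSE], y[tr])
      p <- predict_prob(m, x[!tr, , drop = FALSE])
      cm <- confusion(y[!tr], as.integer(p >= 0.5))
      mcc(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]])
    }, numeric(1)))
  }
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  log <- pts
  log$stage <- "grid"
  log$cv_mcc <- vapply(seq_len(nrow(pts)),
                       function(i) score(as.list(pts[i, , drop = FALSE])),
                       numeric(1))
  # stage 2: random sampling within the hyper-box of the top grid points
  if (n_refine > 0L && nrow(pts) > 1L) {
    top <- log[order(-log$cv_mcc), , drop = FALSE]
    top <- top[seq_len(max(1L, ceiling(nrow(top) / 4))), , drop = FALSE]
    set.seed(seed + 1L)
    ref <- lapply(seq_len(n_refine), function(i) {
      hp <- lapply(names(grid), function(nm) {
        v <- top[[nm]]
        if (is.numeric(v) && length(unique(v)) > 1L) {
          s <- stats::runif(1, min(v), max(v))
          if (all(v == round(v))) s <- as.integer(round(s))
          s
        } else v[[sample.int(length(v), 1L)]]
      })
      names(hp) <- names(grid)
      hp
    })
    ref_log <- do.call(rbind, lapply(ref, as.data.frame))
    ref_log$stage <- "refine"
    ref_log$cv_mcc <- vapply(ref, score, numeric(1))
    log <- rbind(log, ref_log)
  }
  best <- log[which.max(log$cv_mcc), , drop = FALSE]
  hp <- as.list(best[, setdiff(names(best), c("stage", "cv_mcc")),
                     drop = FALSE])
  list(spec = classifier_spec(method, hp, seed = seed),
       best_mcc = best$cv_mcc, log = log)
}

.default_grid <- function(method) {
  switch(method,
    nb = list(laplace = c(0, 1)),
    knn_weighted = list(k = c(3L, 5L, 7L, 9L, 15L)),
    rlr = list(alpha = c(0, 0.5, 1), lambda = c(0.001, 0.01, 0.1)),
    svm_rbf = list(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    sgb = list(nrounds = c(50L, 150L), eta = c(0.05, 0.2),
               max_depth = c(2L, 4L), subsample = c(0.5, 0.8)),
    xgboost = list(nrounds = c(50L, 150L), eta = c(0.05, 0.2),
                   max_depth = c(2L, 4L, 6L)),
    dnn = list(hidden = c(16L, 64L), n_layers = c(2L, 3L),
               learning_rate = c(0.001, 0.01)),
    stop("unknown method: ", method)
  )
}

#' Majority-vote consensus of class labels
#'
#' Combines an odd number of aligned prediction sets by unweighted majority
#' vote of their hard labels; the consensus probability is the vote
#' fraction.
#'
#' @param prediction_sets list of [prediction_set()]s over the same
#'   compounds in the same order; the count must be odd.
#' @return a [prediction_set()].
#' @export
consensus_label <- function(prediction_sets) {
  .check_aligned(prediction_sets)
  if (length(prediction_sets) %% 2L == 0L) {
    stop("label consensus needs an odd number of members (tie risk)")
  }
  votes <- Reduce(`+`, lapply(prediction_sets, `[[`, "predicted_label")) /
    length(prediction_sets)
  prediction_set(prediction_sets[[1L]]$compound_id, votes)
}

#' Mean-probability consensus
#'
#' Combines aligned prediction sets by the unweighted mean of their
#' inhibitor probabilities; labels follow the 0.5 threshold.
#'
#' @inheritParams consensus_label
#' @return a [prediction_set()].
#' @export
consensus_probability <- function(prediction_sets) {
  .check_aligned(prediction_sets)
  p <- Reduce(`+`, lapply(prediction_sets, `[[`, "p_inhibitor")) /
    length(prediction_sets)
  prediction_set(prediction_sets[[1L]]$compound_id, p)
}

.check_aligned <- function(prediction_sets) {
  stopifnot(length(prediction_sets) >= 1L)
  ids <- prediction_sets[[1L]]$compound_id
  for (ps in prediction_sets) {
    if (!inherits(ps, "prediction_set")) stop("members must be prediction_sets")
    if (!identical(ps$compound_id, ids)) stop("prediction sets not aligned")
  }
  invisible(TRUE)
}
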