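# Orchestration: configuration, file adapters, and the end-to-end pipeline
# run (curate -> featurize -> filter -> split -> select -> train -> evaluate
# -> interpret -> applicability domain -> fragments).

.CONFIG_KEYS <- c(
  "seed", "out_dir", "test_fraction", "nzv_freq_cut", "nzv_unique_cut",
  "correlation_threshold", "run_sa_selection", "sa", "methods",
  "consensus_members", "cv_folds", "cluster_distance_threshold",
  "run_cluster_cv", "ad_variance", "importance_repeats", "run_fragments",
  "fragment_top_n"
)

#' Pipeline configuration
#'
#' Validated key-value configuration for [run_pipeline()]. Unknown keys are
#' rejected before any computation. A persisted configuration plus its seed
#' reruns to identical outputs for the deterministic stages.
#'
#' @param seed master seed threaded into every random stage.
#' @param out_dir artifact directory (created if missing).
#' @param test_fraction held-out fraction per class (default 1/5).
#' @param nzv_freq_cut,nzv_unique_cut near-zero-variance filter cutoffs.
#' @param correlation_threshold pairwise-correlation cutoff (default 0.90).
#' @param run_sa_selection run the SA feature search (default TRUE).
#' @param sa an [sa_config()] (seed is overridden by the master seed).
#' @param methods classifier methods to train (default the three
#'   consensus members: `svm_rbf`, `xgboost`, `dnn`).
#' @param consensus_members methods combined by the consensus models.
#' @param cv_folds folds of the random cross-validation (default 5).
#' @param run_cluster_cv also run Tanimoto-cluster cross-validation.
#' @param cluster_distance_threshold dendrogram cut (default 0.7).
#' @param ad_variance variance retained by the AD projection (default 0.95).
#' @param importance_repeats permutation repetitions (default 10).
#' @param run_fragments run fragment enrichment (default TRUE).
#' @param fragment_top_n rows per ranked fragment list (default 10).
#' @param ... rejected: any unknown key is an error.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("bcrp_run_"),
                            test_fraction = 1 / 5,
                            nzv_freq_cut = 95 / 5, nzv_unique_cut = 10,
                            correlation_threshold = 0.90,
                            run_sa_selection = TRUE, sa = sa_config(),
                            methods = c("svm_rbf", "xgboost", "dnn"),
                            consensus_members = c("svm_rbf", "xgboost", "dnn"),
                            cv_folds = 5L, run_cluster_cv = TRUE,
                            cluster_distance_threshold = 0.7,
                            ad_variance = 0.95, importance_repeats = 10L,
                            run_fragments = TRUE, fragment_top_n = 10L,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(all(methods %in% .METHODS), all(consensus_members %in% .METHODS))
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              test_fraction = test_fraction, nzv_freq_cut = nzv_freq_cut,
              nzv_unique_cut = nzv_unique_cut,
              correlation_threshold = correlation_threshold,
              run_sa_selection = run_sa_selection, sa = sa,
              methods = methods, consensus_members = consensus_members,
              cv_folds = as.integer(cv_folds),
              run_cluster_cv = run_cluster_cv,
              cluster_distance_threshold = cluster_distance_threshold,
              ad_variance = ad_variance,
              importance_repeats = as.integer(importance_repeats),
              run_fragments = run_fragments,
              fragment_top_n = as.integer(fragment_top_n))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a SMILES compound table from CSV
#'
#' Expects at least `compound_id` and `smiles` columns (an optional `label`
#' column is kept). Records whose SMILES fail to parse are skipped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @return data.frame of loadable compounds; attribute `n_skipped` counts
#'   rejected records.
#' @export
read_compounds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !("compound_id" %in% names(df))) {
    names(df)[names(df) == "id"] <- "compound_id"
  }
  stopifnot(all(c("compound_id", "smiles") %in% names(df)))
  if (nrow(df) == 0L) stop("no compounds in ", path)
  can <- canonical_smiles(df$smiles)
  bad <- is.na(can)
  if (all(bad)) stop("no compounds could be parsed from ", path)
  if (any(bad)) {
    message(sum(bad), " malformed record(s) skipped in ", basename(path))
  }
  out <- df[!bad, , drop = FALSE]
  out$canonical_smiles <- can[!bad]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a labeled compound table to CSV
#'
#' @param compounds data.frame with `compound_id`, `smiles` (or
#'   `canonical_smiles`) and `label`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_compounds_csv <- function(compounds, path) {
  smi <- if (!is.null(compounds$canonical_smiles)) {
    compounds$canonical_smiles
  } else compounds$smiles
  utils::write.csv(
    data.frame(id = compounds$compound_id, smiles = smi,
               label = compounds$label),
    path, row.names = FALSE)
  invisible(path)
}

#' Read compound structures from an SDF file
#'
#' @param path SDF file path.
#' @return data.frame with `compound_id` and canonical `smiles`.
#' @export
read_sdf_compounds <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- suppressWarnings(as.character(ChemmineR::sdf2smiles(sdf)))
  data.frame(compound_id = ChemmineR::cid(sdf),
             smiles = canonical_smiles(smi),
             stringsAsFactors = FALSE)
}

#' Read an activity-record table from CSV
#'
#' @param path CSV with columns `compound_id`, `smiles`, `index_type` and
#'   optionally `value`, `concentration`, `outcome`, `source_id`.
#' @return data.frame of activity records.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "smiles", "index_type") %in% names(df)))
  if (nrow(df) == 0L) stop("no records in ", path)
  df
}

#' Run the full QSAR pipeline on a labeled compound library
#'
#' Executes the stages in order -- featurization, near-zero-variance and
#' correlation filtering, stratified 4:1 split, training-statistics
#' normalization, optional SA feature selection, model training, random
#' (and optionally cluster) cross-validation plus test-set evaluation,
#' consensus models, permutation importance, applicability-domain coverage,
#' and fragment enrichment -- writing each artifact plus a JSON manifest
#' under `config$out_dir`.
#'
#' @param compounds labeled compound data.frame (`compound_id`, `smiles`,
#'   `label`), e.g. from [curate_dataset()] or [gen_compound_library()].
#' @param config a [pipeline_config()].
#' @return list of in-memory results (metrics, selected features, AD
#'   summary, fragment tables, importance tables, artifact paths).
#' @export
run_pipeline <- function(compounds, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fm <- stage("featurize", compute_features(compounds))
  keep <- stage("nzv_filter",
                near_zero_variance_filter(fm, config$nzv_freq_cut,
                                          config$nzv_unique_cut))
  fm1 <- fm_subset(fm, features = keep)
  keep2 <- stage("correlation_filter",
                 correlation_filter(fm1, config$correlation_threshold))
  fm2 <- fm_subset(fm1, features = keep2)

  split <- stage("split", stratified_split(fm2$labels, config$test_fraction,
                                           seed = config$seed))
  train_fm <- fm_subset(fm2, rows = split$train)
  test_fm <- fm_subset(fm2, rows = split$test)
  norm <- stage("normalize", normalize_features(train_fm))
  train_fm <- norm$fm
  test_fm <- stage("normalize_test",
                   normalize_features(test_fm, stats = norm$stats)$fm)

  selected <- colnames(train_fm$x)
  sa_trace <- NULL
  if (config$run_sa_selection) {
    cfg <- config$sa
    cfg$seed <- config$seed
    sa_trace <- stage("sa_selection", sa_search(train_fm, config = cfg))
    best <- stage("sa_best", select_best_iteration(sa_trace, train_fm))
    selected <- best$features
    utils::write.csv(sa_trace$trace, file.path(config$out_dir, "sa_trace.csv"),
                     row.names = FALSE)
    writeLines(selected, file.path(config$out_dir, "selected_features.txt"))
  }
  train_sel <- fm_subset(train_fm, features = selected)
  test_sel <- fm_subset(test_fm, features = selected)

  folds <- random_kfold(train_sel$labels, k = config$cv_folds,
                        seed = config$seed)
  metrics <- list()
  importances <- list()
  member_test_preds <- list()
  for (m in config$methods) {
    spec <- classifier_spec(m, seed = config$seed)
    cv <- stage(paste0("cv_", m),
                cross_validate(spec, train_sel$x, train_sel$labels, folds))
    model <- stage(paste0("train_", m),
                   train_classifier(spec, train_sel$x, train_sel$labels))
    p_test <- predict_prob(model, test_sel$x)
    test_metrics <- evaluate_predictions(test_sel$labels, p_test)
    metrics[[m]] <- cbind(model = m, set = c("cv_random", "test"),
                          rbind(cv$metrics, test_metrics))
    member_test_preds[[m]] <- prediction_set(rownames(test_sel$x), p_test)
    if (config$run_cluster_cv) {
      bits <- train_sel$x[, train_sel$kind == "binary_bit", drop = FALSE]
      cl <- stage("cluster_folds",
                  cluster_folds(bits, k = config$cv_folds,
                                distance_threshold =
                                  config$cluster_distance_threshold,
                                seed = config$seed))
      ccv <- cross_validate(spec, train_sel$x, train_sel$labels, cl$fold)
      metrics[[paste0(m, "_cluster")]] <-
        cbind(model = m, set = "cv_cluster", ccv$metrics)
    }
    imp <- stage(paste0("importance_", m),
                 permutation_importance(model, train_sel$x, train_sel$labels,
                                        n_repeats = config$importance_repeats,
                                        seed = config$seed))
    importances[[m]] <- imp
    utils::write.csv(imp, file.path(config$out_dir,
                                    paste0("importance_", m, ".csv")),
                     row.names = FALSE)
  }
  members <- member_test_preds[intersect(config$consensus_members,
                                         names(member_test_preds))]
  if (length(members) >= 2L) {
    if (length(members) %% 2L == 1L) {
      c1 <- consensus_label(unname(members))
      metrics[["consensus_label"]] <- cbind(
        model = "consensus_label", set = "test",
        evaluate_predictions(test_sel$labels, c1$p_inhibitor))
    }
    c2 <- consensus_probability(unname(members))
    metrics[["consensus_probability"]] <- cbind(
      model = "consensus_probability", set = "test",
      evaluate_predictions(test_sel$labels, c2$p_inhibitor))
  }
  metrics_df <- do.call(rbind, metrics)
  rownames(metrics_df) <- NULL
  utils::write.csv(metrics_df, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  ad <- stage("ad", fit_ad(train_sel, variance = config$ad_variance))
  ad_train <- ad_coverage(ad, train_sel)
  ad_test <- ad_coverage(ad, test_sel)
  ad_summary <- rbind(cbind(set = "train", ad_train$summary),
                      cbind(set = "test", ad_test$summary))
  utils::write.csv(ad_summary, file.path(config$out_dir, "ad_summary.csv"),
                   row.names = FALSE)

  frag <- NULL
  if (config$run_fragments) {
    frag_tab <- stage("fragments", fragment_table(compounds))
    frag <- rank_fragments(frag_tab, config$fragment_top_n)
    utils::write.csv(frag$positive,
                     file.path(config$out_dir, "fragments_positive.csv"),
                     row.names = FALSE)
    utils::write.csv(frag$negative,
                     file.path(config$out_dir, "fragments_negative.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bcrpqsar")),
    seed = config$seed,
    n_compounds = nrow(compounds),
    n_features_raw = ncol(fm$x),
    n_features_filtered = ncol(fm2$x),
    n_features_selected = length(selected),
    split = list(train = length(split$train), test = length(split$test)),
    methods = config$methods,
    parameters = config[setdiff(names(config), c("sa", "out_dir"))]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(metrics = metrics_df, selected_features = selected,
       sa_trace = sa_trace, ad = ad_summary, fragments = frag,
       importance = importances, out_dir = config$out_dir,
       split = split)
}
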