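# Featurization: molecular features, pre-filters, splitting, normalization,
# and the simple-descriptor class comparison.

#' Construct a feature matrix
#'
#' Lightweight container aligning a numeric compound-by-feature table with a
#' per-feature kind tag (`"continuous"` descriptor vs `"binary_bit"`
#' fingerprint bit) and optional 0/1 labels.
#'
#' @param x numeric matrix, rownames = compound ids, colnames = feature
#'   names; must be complete (no missing values).
#' @param kind named character vector over `colnames(x)` with values
#'   `"continuous"` or `"binary_bit"`.
#' @param labels optional 0/1 vector aligned with rows.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, kind, labels = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature names required")
  if (is.null(rownames(x))) rownames(x) <- paste0("cmp", seq_len(nrow(x)))
  if (anyNA(x)) stop("feature matrix must be complete (no missing values)")
  if (!all(colnames(x) %in% names(kind))) stop("kind must cover all features")
  kind <- kind[colnames(x)]
  if (!all(kind %in% c("continuous", "binary_bit"))) {
    stop("kind must be 'continuous' or 'binary_bit'")
  }
  bit_cols <- names(kind)[kind == "binary_bit"]
  bad <- bit_cols[vapply(bit_cols, function(nm) !all(x[, nm] %in% c(0, 1)),
                         logical(1))]
  if (length(bad)) stop("binary_bit columns must contain only {0,1}: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("labels must align with rows")
    .check_binary(labels)
    labels <- as.integer(labels)
  }
  structure(list(x = x, kind = kind, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "compounds x", ncol(x$x), "features (",
      sum(x$kind == "continuous"), "continuous,",
      sum(x$kind == "binary_bit"), "binary )\n")
  if (!is.null(x$labels)) {
    cat("labels: ", sum(x$labels == 1L), "inhibitors /",
        sum(x$labels == 0L), "non-inhibitors\n")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# Subset a feature matrix by rows and/or feature names.
#' Subset a feature matrix
#' @param fm a [feature_matrix()].
#' @param rows row indices or logical mask (default all).
#' @param features feature names or column indices (default all).
#' @return a new `feature_matrix`.
#' @export
fm_subset <- function(fm, rows = NULL, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(fm$x))
  if (is.null(features)) features <- colnames(fm$x)
  feature_matrix(fm$x[rows, features, drop = FALSE], fm$kind[features],
                 if (is.null(fm$labels)) NULL else fm$labels[rows])
}

#' Compute molecular features for standardized structures
#'
#' Continuous descriptors (namespaced `desc:`) are computed with OpenBabel
#' plus graph-derived counts: molecular weight, logP, an ESOL-style logS
#' estimate, topological polar surface area, molar refractivity, H-bond
#' acceptor/donor counts, heavy-atom/bond/ring counts, rotatable bonds, Kier
#' flexibility index, and aromatic atom/bond counts. Binary substructure
#' bits (namespaced `fp:`) come from the OpenBabel FP2 1024-bit path
#' fingerprint. Compounds that fail to parse are dropped with a message;
#' feature columns containing missing values are removed.
#'
#' @param compounds data.frame with columns `compound_id`, `smiles` and
#'   optionally `label`, or a character vector of SMILES.
#' @param fingerprint OpenBabel fingerprint name (default `"FP2"`).
#' @return a [feature_matrix()] (labels attached when present); attribute
#'   `dropped_compounds` lists ids that failed.
#' @export
compute_features <- function(compounds, fingerprint = "FP2") {
  if (is.character(compounds)) {
    compounds <- data.frame(compound_id = paste0("cmp", seq_along(compounds)),
                            smiles = compounds, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  parsed <- .parse_smiles_set(compounds$smiles, compounds$compound_id)
  if (!any(parsed$valid)) stop("no compounds could be parsed")
  if (any(!parsed$valid)) {
    message(sum(!parsed$valid), " compound(s) failed descriptor computation ",
            "and were dropped: ",
            paste(utils::head(compounds$compound_id[!parsed$valid], 5),
                  collapse = ", "))
  }
  sdf <- parsed$sdf
  desc <- .descriptor_block(sdf)
  fp <- ChemmineR::fingerprintOB(sdf, fingerprint)
  bits <- methods::slot(fp, "fpma")
  storage.mode(bits) <- "double"
  colnames(bits) <- paste0("fp:", fingerprint, ".", seq_len(ncol(bits)))
  rownames(bits) <- rownames(desc)
  x <- cbind(desc, bits)
  # drop features with any missing value
  keep <- colSums(is.na(x)) == 0L
  x <- x[, keep, drop = FALSE]
  kind <- c(rep("continuous", ncol(desc)), rep("binary_bit", ncol(bits)))
  names(kind) <- c(colnames(desc), colnames(bits))
  kind <- kind[colnames(x)]
  labels <- NULL
  if (!is.null(compounds$label)) labels <- compounds$label[parsed$valid]
  fm <- feature_matrix(x, kind, labels)
  attr(fm, "dropped_compounds") <- compounds$compound_id[!parsed$valid]
  fm
}

# Continuous descriptor block for an SDFset (rownames = compound ids).
.descriptor_block <- function(sdf) {
  ids <- ChemmineR::cid(sdf)
  props <- ChemmineR::propOB(sdf)
  n <- length(sdf)
  g_desc <- t(vapply(seq_len(n), function(i) .graph_descriptors(sdf[[i]]),
                     numeric(7)))
  logp <- props$logP
  mw <- props$MW
  # ESOL-style aqueous solubility estimate (Delaney-type linear model)
  ap <- ifelse(g_desc[, "heavy_atoms"] > 0,
               g_desc[, "aromatic_atoms"] / g_desc[, "heavy_atoms"], 0)
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw +
    0.066 * g_desc[, "rotatable_bonds"] - 0.74 * ap
  out <- cbind(
    `desc:MW` = mw, `desc:logP` = logp, `desc:logS` = logs,
    `desc:TPSA` = props$TPSA, `desc:MR` = props$MR,
    `desc:HBA` = props$HBA1, `desc:HBD` = props$HBD,
    `desc:heavy_atoms` = g_desc[, "heavy_atoms"],
    `desc:bonds` = g_desc[, "bonds"],
    `desc:rings` = g_desc[, "rings"],
    `desc:rotatable_bonds` = g_desc[, "rotatable_bonds"],
    `desc:kier_flex` = g_desc[, "kier_flex"],
    `desc:aromatic_atoms` = g_desc[, "aromatic_atoms"],
    `desc:aromatic_bonds` = g_desc[, "aromatic_bonds"]
  )
  rownames(out) <- ids
  out
}

# Graph-derived descriptors of one SDF molecule (heavy-atom graph).
.graph_descriptors <- function(sdf_single) {
  bt <- .bond_table(sdf_single)
  n_atoms <- nrow(ChemmineR::atomblock(sdf_single))
  n_bonds <- nrow(bt)
  n_rings <- n_bonds - n_atoms + 1L  # cyclomatic number (connected molecule)
  arom <- .aromatic_atoms_bonds(sdf_single, bt)
  deg <- tabulate(c(bt$a, bt$b), nbins = n_atoms)
  ring_bond <- .ring_bond_mask(bt, n_atoms)
  # rotatable: acyclic single bonds between two non-terminal heavy atoms
  rot <- sum(bt$order == 1L & !ring_bond & deg[bt$a] > 1L & deg[bt$b] > 1L)
  # Kier flexibility from kappa shape indices (heavy-atom counts of paths)
  p1 <- n_bonds
  p2 <- sum(choose(deg, 2))
  kappa1 <- if (p1 > 0) n_atoms * (n_atoms - 1)^2 / p1^2 else 0
  kappa2 <- if (p2 > 0) (n_atoms - 1) * (n_atoms - 2)^2 / p2^2 else 0
  kflex <- if (n_atoms > 0) kappa1 * kappa2 / n_atoms else 0
  c(heavy_atoms = n_atoms, bonds = n_bonds, rings = max(n_rings, 0L),
    rotatable_bonds = rot, kier_flex = kflex,
    aromatic_atoms = arom[["atoms"]], aromatic_bonds = arom[["bonds"]])
}

# Logical mask over bonds: bond participates in a ring (non-bridge edge).
.ring_bond_mask <- function(bt, n_atoms) {
  if (nrow(bt) == 0L) return(logical(0))
  g <- igraph::graph_from_data_frame(bt[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n_atoms)))
  br <- igraph::bridges(g)
  mask <- rep(TRUE, nrow(bt))
  mask[as.integer(br)] <- FALSE
  mask
}

# Aromatic atom and bond counts via ChemmineR aromatic-ring perception.
.aromatic_atoms_bonds <- function(sdf_single, bt) {
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf_single, upper = 7, type = "arom",
                                      arom = TRUE)),
    error = function(e) NULL)
  arom_rings <- rings$AROMATIC_RINGS
  if (is.null(arom_rings) || length(arom_rings) == 0L) {
    return(c(atoms = 0, bonds = 0))
  }
  atom_ids <- unique(unlist(lapply(arom_rings, function(r)
    as.integer(sub(".*_", "", r)))))
  in_arom <- bt$a %in% atom_ids & bt$b %in% atom_ids
  ring_mask <- .ring_bond_mask(bt, nrow(ChemmineR::atomblock(sdf_single)))
  c(atoms = length(atom_ids), bonds = sum(in_arom & ring_mask))
}

#' Near-zero-variance feature filter
#'
#' Removes features that are constant (one unique value) or that combine a
#' large frequency gap between the two most common values
#' (ratio > `freq_cut`) with very few distinct values
#' (percent unique < `unique_cut`).
#'
#' @param fm a [feature_matrix()] or numeric matrix.
#' @param freq_cut most-common / second-most-common frequency ratio cutoff
#'   (default 95/5).
#' @param unique_cut percent-unique-values cutoff (default 10).
#' @return character vector of retained feature names.
#' @export
near_zero_variance_filter <- function(fm, freq_cut = 95 / 5, unique_cut = 10) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  keep <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) == 1L) return(FALSE)
    freq_ratio <- tab[1L] / tab[2L]
    pct_unique <- 100 * length(tab) / length(col)
    !(freq_ratio > freq_cut && pct_unique < unique_cut)
  }, logical(1))
  colnames(x)[keep]
}

#' Pairwise-correlation feature filter
#'
#' Greedy elimination of highly correlated features: while any absolute
#' Pearson correlation exceeds `threshold`, the worst pair is found and the
#' member with the larger mean absolute correlation against all remaining
#' features is removed (ties broken by column order, keeping the earlier
#' column).
#'
#' @param fm a [feature_matrix()] or numeric matrix (must be complete and
#'   free of zero-variance columns -- run the near-zero-variance filter
#'   first).
#' @param threshold absolute correlation above which one of a pair is
#'   removed (default 0.90).
#' @return character vector of retained feature names (original order).
#' @export
correlation_filter <- function(fm, threshold = 0.90) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column present; apply near_zero_variance_filter first")
  }
  cm <- abs(stats::cor(x))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(x))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (all(sub <= threshold)) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    nm <- rownames(sub)[worst]
    m1 <- mean(sub[nm[1L], ])
    m2 <- mean(sub[nm[2L], ])
    drop_nm <- if (m1 > m2) nm[1L] else if (m2 > m1) nm[2L] else
      nm[which.max(match(nm, colnames(x)))]  # tie: drop the later column
    alive[match(drop_nm, colnames(x))] <- FALSE
  }
  colnames(x)[alive]
}

#' Stratified train/test split
#'
#' Splits a labeled dataset 4:1 (by default) with stratified sampling: per
#' class, `floor(class_size * test_fraction)` compounds go to the test set,
#' drawn uniformly at random under the seed; the remainder trains. This
#' floor rule reproduces an exact printed partition from given class sizes.
#'
#' @param labels 0/1 labels.
#' @param test_fraction fraction of each class held out (default 1/5).
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 1 / 5, seed = 1L) {
  .check_binary(labels)
  if (min(table(factor(labels, levels = c(0, 1)))) < 5) {
    stop("each class needs at least 5 members")
  }
  set.seed(seed)
  test <- integer(0)
  for (cls in c(1L, 0L)) {
    ix <- which(labels == cls)
    n_test <- floor(length(ix) * test_fraction)
    test <- c(test, sort(sample(ix, n_test)))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Normalize continuous features with training statistics
#'
#' Continuous features are scaled to zero mean / unit variance using
#' statistics computed from the training rows only; binary fingerprint bits
#' are left untouched. Apply the returned statistics to the test set so no
#' test information leaks into the transformation.
#'
#' @param fm a [feature_matrix()].
#' @param stats optional list with `mean` and `sd` (named over continuous
#'   features) computed from training data; when `NULL` they are computed
#'   from `fm` itself.
#' @return list with `fm` (transformed [feature_matrix()]) and `stats`.
#' @export
normalize_features <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  cont <- names(fm$kind)[fm$kind == "continuous"]
  if (is.null(stats)) {
    mu <- colMeans(fm$x[, cont, drop = FALSE])
    sd_ <- apply(fm$x[, cont, drop = FALSE], 2, stats::sd)
    if (any(sd_ == 0)) {
      stop("zero-variance continuous feature: ",
           paste(utils::head(cont[sd_ == 0], 3), collapse = ", "))
    }
    stats <- list(mean = mu, sd = sd_)
  }
  x <- fm$x
  x[, cont] <- sweep(sweep(x[, cont, drop = FALSE], 2, stats$mean[cont]),
                     2, stats$sd[cont], "/")
  list(fm = feature_matrix(x, fm$kind, fm$labels), stats = stats)
}

#' Compare simple property distributions between classes
#'
#' Computes the eight interpretable descriptors (logP, logS estimate, H-bond
#' acceptor and donor counts, rotatable bonds, Kier flexibility, aromatic
#' atom and bond counts) per compound, then reports per-class means and a
#' two-sided Mann-Whitney U-test p-value per descriptor.
#'
#' @param compounds data.frame with `compound_id` and `smiles`, or SMILES
#'   character vector.
#' @param labels 0/1 labels aligned with compounds.
#' @return data.frame with one row per descriptor: `descriptor`,
#'   `mean_inhibitor`, `mean_noninhibitor`, `p_value`.
#' @export
compare_property_distributions <- function(compounds, labels) {
  .check_binary(labels)
  if (min(table(labels)) < 2) stop("each class needs at least 2 members")
  fm <- compute_features(if (is.character(compounds))
    data.frame(compound_id = paste0("cmp", seq_along(compounds)),
               smiles = compounds, label = labels,
               stringsAsFactors = FALSE)
    else cbind(compounds, label = labels))
  props <- c("desc:logP", "desc:logS", "desc:HBA", "desc:HBD",
             "desc:rotatable_bonds", "desc:kier_flex",
             "desc:aromatic_atoms", "desc:aromatic_bonds")
  props <- intersect(props, colnames(fm$x))
  y <- fm$labels
  out <- lapply(props, function(p) {
    v1 <- fm$x[y == 1L, p]
    v0 <- fm$x[y == 0L, p]
    pv <- tryCatch(
      stats::wilcox.test(v1, v0, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(descriptor = p, mean_inhibitor = mean(v1),
               mean_noninhibitor = mean(v0), p_value = pv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
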