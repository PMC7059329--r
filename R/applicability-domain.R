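# Applicability domain: non-parametric probability-density estimate over the
# training feature space, with coverage reporting.

#' Fit a density-based applicability domain
#'
#' Projects the (normalized) training features onto the principal components
#' retaining at least `variance` of the total variance, fits a Gaussian
#' product-kernel density estimate with Scott's bandwidth per component, and
#' sets the domain threshold at the `threshold_quantile` quantile of the
#' training densities. The default quantile 0 (the minimum training density)
#' makes every training compound fall inside its own domain.
#'
#' @param fm a [feature_matrix()] or numeric matrix of normalized training
#'   features.
#' @param variance fraction of variance the projection must retain
#'   (default 0.95).
#' @param threshold_quantile quantile of training densities used as the
#'   inside/outside threshold (default 0).
#' @return object of class `ad_model` with the projection, bandwidths,
#'   training densities and threshold.
#' @export
fit_ad <- function(fm, variance = 0.95, threshold_quantile = 0) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  n <- nrow(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  d <- max(1L, which(cum >= variance)[1L])
  if (is.na(d) || d > n - 2L) {
    stop("too few compounds (", n, ") to retain ", variance,
         " of the variance: the density estimate would need ", d,
         " dimensions")
  }
  z <- pc$x[, seq_len(d), drop = FALSE]
  # Scott's rule per retained component
  h <- apply(z, 2, stats::sd) * n^(-1 / (d + 4))
  h[h == 0] <- 1e-8
  model <- structure(list(rotation = pc$rotation[, seq_len(d), drop = FALSE],
                          center = pc$center, bandwidth = h, train = z,
                          n_components = d,
                          variance_explained = cum[d]),
                     class = "ad_model")
  dens <- ad_density(model, x)
  model$train_density <- dens
  model$threshold <- stats::quantile(dens, threshold_quantile, names = FALSE)
  model
}

#' Evaluate the AD density at query compounds
#'
#' @param ad an `ad_model` from [fit_ad()].
#' @param fm query features in the same (pre-projection) feature space.
#' @return numeric density per query compound.
#' @export
ad_density <- function(ad, fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  z <- sweep(x, 2, ad$center) %*% ad$rotation
  h <- ad$bandwidth
  tr <- ad$train
  vapply(seq_len(nrow(z)), function(i) {
    u <- sweep(tr, 2, z[i, ], "-")
    logk <- -0.5 * sweep(u^2, 2, h^2, "/")
    logk <- sweep(logk, 2, log(h * sqrt(2 * pi)), "-")
    mean(exp(rowSums(logk)))
  }, numeric(1))
}

#' Applicability-domain coverage report
#'
#' Classifies each query compound as inside (density at or above the fitted
#' threshold) or outside the domain and reports per-class counts and the
#' coverage percentage.
#'
#' @param ad an `ad_model`.
#' @param fm query features (same feature space as the training matrix).
#' @param labels optional 0/1 labels for the per-class breakdown.
#' @return list with `per_compound` (data.frame `density`, `inside`) and
#'   `summary` (inside/outside counts split by class plus `coverage_pct`).
#' @export
ad_coverage <- function(ad, fm, labels = NULL) {
  stopifnot(inherits(ad, "ad_model"))
  x <- if (inherits(fm, "feature_matrix")) {
    if (is.null(labels)) labels <- fm$labels
    fm$x
  } else as.matrix(fm)
  if (ncol(x) != length(ad$center)) stop("feature space mismatch")
  dens <- ad_density(ad, x)
  inside <- dens >= ad$threshold
  per <- data.frame(density = dens, inside = inside)
  if (is.null(labels)) labels <- rep(NA_integer_, nrow(x))
  summary <- data.frame(
    inside_inhibitors = sum(inside & labels == 1L, na.rm = TRUE),
    inside_noninhibitors = sum(inside & labels == 0L, na.rm = TRUE),
    outside_inhibitors = sum(!inside & labels == 1L, na.rm = TRUE),
    outside_noninhibitors = sum(!inside & labels == 0L, na.rm = TRUE),
    n_inside = sum(inside), n_outside = sum(!inside),
    coverage_pct = 100 * mean(inside)
  )
  list(per_compound = per, summary = summary)
}
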