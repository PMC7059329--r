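# Synthetic-data generators. These emulate the three pipeline inputs --
# activity-record tables, labeled SMILES libraries with planted ring-system
# fragments, and numeric feature tables with a known informative subset --
# so every stage can be exercised and tested without any download.

#' Specification of a synthetic dataset
#'
#' Continuous features are unit-variance normals, so `effect_size` is
#' directly a Cohen's d between classes and the separability of a single
#' informative feature is the closed-form normal overlap. Fingerprint bits
#' are Bernoulli draws with class-dependent rates.
#'
#' @param n_inhibitors,n_noninhibitors class sizes.
#' @param n_informative_continuous,n_noise_continuous continuous feature
#'   counts; informative ones have class means separated by `effect_size`.
#' @param n_fingerprint_bits number of binary fingerprint-like features.
#' @param effect_size standardized mean shift (Cohen's d) of informative
#'   continuous features; must be finite.
#' @param bit_rate_inhibitor,bit_rate_noninhibitor Bernoulli rates of the
#'   fingerprint bits per class, in \[0, 1\].
#' @param planted_fragments data.frame with columns `scaffold` (SMILES),
#'   `rate_inhibitor`, `rate_noninhibitor`, for [gen_compound_library()].
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_inhibitors = 100L, n_noninhibitors = 100L,
                           n_informative_continuous = 5L,
                           n_noise_continuous = 20L,
                           n_fingerprint_bits = 32L,
                           effect_size = 1,
                           bit_rate_inhibitor = 0.5,
                           bit_rate_noninhibitor = 0.5,
                           planted_fragments = NULL,
                           seed = 1L) {
  counts <- c(n_inhibitors, n_noninhibitors, n_informative_continuous,
              n_noise_continuous, n_fingerprint_bits)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  rates <- c(bit_rate_inhibitor, bit_rate_noninhibitor)
  if (any(rates < 0 | rates > 1)) stop("bit rates must lie in [0, 1]")
  if (!is.null(planted_fragments)) {
    stopifnot(is.data.frame(planted_fragments),
              all(c("scaffold", "rate_inhibitor", "rate_noninhibitor") %in%
                    names(planted_fragments)))
    pr <- c(planted_fragments$rate_inhibitor,
            planted_fragments$rate_noninhibitor)
    if (any(pr < 0 | pr > 1)) stop("fragment rates must lie in [0, 1]")
  }
  structure(list(
    n_inhibitors = as.integer(n_inhibitors),
    n_noninhibitors = as.integer(n_noninhibitors),
    n_informative_continuous = as.integer(n_informative_continuous),
    n_noise_continuous = as.integer(n_noise_continuous),
    n_fingerprint_bits = as.integer(n_fingerprint_bits),
    effect_size = effect_size,
    bit_rate_inhibitor = bit_rate_inhibitor,
    bit_rate_noninhibitor = bit_rate_noninhibitor,
    planted_fragments = planted_fragments,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a labeled synthetic feature table
#'
#' Informative continuous features are drawn `N(effect_size, 1)` for
#' inhibitors and `N(0, 1)` for non-inhibitors; noise features are `N(0, 1)`
#' in both classes; fingerprint bits are Bernoulli with the class rates.
#' Feature names record the ground truth: `inf_cont_*` are informative,
#' `noise_cont_*` are not, `fp_bit_*` are binary.
#'
#' @param spec a [synthetic_spec()].
#' @return a [feature_matrix()] with labels; attribute `informative` names
#'   the informative features.
#' @export
gen_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_inhibitors
  n0 <- spec$n_noninhibitors
  n <- n1 + n0
  labels <- c(rep(1L, n1), rep(0L, n0))
  p_inf <- spec$n_informative_continuous
  p_noise <- spec$n_noise_continuous
  p_bit <- spec$n_fingerprint_bits

  inf <- matrix(stats::rnorm(n * p_inf), n, p_inf)
  if (p_inf > 0L && n1 > 0L) {
    inf[seq_len(n1), ] <- inf[seq_len(n1), , drop = FALSE] + spec$effect_size
  }
  noise <- matrix(stats::rnorm(n * p_noise), n, p_noise)
  bits <- matrix(0L, n, p_bit)
  if (p_bit > 0L) {
    if (n1 > 0L) bits[seq_len(n1), ] <-
        stats::rbinom(n1 * p_bit, 1L, spec$bit_rate_inhibitor)
    if (n0 > 0L) bits[n1 + seq_len(n0), ] <-
        stats::rbinom(n0 * p_bit, 1L, spec$bit_rate_noninhibitor)
  }
  x <- cbind(inf, noise, bits)
  colnames(x) <- c(.seq_names("inf_cont_", p_inf),
                   .seq_names("noise_cont_", p_noise),
                   .seq_names("fp_bit_", p_bit))
  rownames(x) <- paste0("cmp", seq_len(n))
  kind <- c(rep("continuous", p_inf + p_noise), rep("binary_bit", p_bit))
  names(kind) <- colnames(x)
  fm <- feature_matrix(x, kind, labels)
  attr(fm, "informative") <- .seq_names("inf_cont_", p_inf)
  fm
}

.seq_names <- function(prefix, p) {
  if (p == 0L) return(character(0))
  paste0(prefix, seq_len(p))
}

#' Default planted-scaffold vocabulary
#'
#' Common ring systems of BCRP inhibitor/non-inhibitor fragment analyses
#' (quinazoline, morpholine, thiophene, piperazine, pyridine) for use as
#' `planted_fragments` scaffolds in [synthetic_spec()].
#'
#' @return data.frame with columns `name` and `scaffold` (SMILES).
#' @export
default_scaffolds <- function() {
  data.frame(
    name = c("quinazoline", "morpholine", "thiophene", "piperazine",
             "pyridine"),
    scaffold = c("c1ccc2ncncc2c1", "C1COCCN1", "c1ccsc1", "C1CNCCN1",
                 "c1ccncc1"),
    stringsAsFactors = FALSE
  )
}

#' Generate a labeled synthetic compound library with planted fragments
#'
#' Each compound is built from a base ring plus the planted scaffolds drawn
#' independently with the class-dependent inclusion rates of the spec, then
#' decorated with a small substituent vocabulary (methyl, chloro, methoxy).
#' Assembly is by direct SMILES concatenation (single bonds between ring
#' systems), so every planted scaffold remains an intact ring assembly that
#' [decompose()] can recover.
#'
#' @param spec a [synthetic_spec()]; `planted_fragments` may be `NULL`
#'   (library of decorated single-ring compounds).
#' @return data.frame with columns `compound_id`, `smiles`, `label`, plus a
#'   logical ground-truth membership column `has_<scaffold>` per planted
#'   fragment (attribute `fragment_smiles` maps those columns to canonical
#'   scaffold SMILES).
#' @export
gen_compound_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  planted <- spec$planted_fragments
  if (!is.null(planted) && nrow(planted) > 0L) {
    can <- canonical_smiles(planted$scaffold)
    if (anyNA(can)) {
      stop("invalid scaffold SMILES: ",
           paste(planted$scaffold[is.na(can)], collapse = ", "))
    }
  } else {
    planted <- data.frame(scaffold = character(),
                          rate_inhibitor = numeric(),
                          rate_noninhibitor = numeric())
    can <- character(0)
  }
  set.seed(spec$seed + 1L)
  n1 <- spec$n_inhibitors
  n0 <- spec$n_noninhibitors
  labels <- c(rep(1L, n1), rep(0L, n0))
  n <- n1 + n0
  bases <- c("c1ccccc1", "C1CCCCC1", "C1CCCC1")
  subs <- c("C", "Cl", "OC")  # methyl, chloro, methoxy
  nf <- nrow(planted)
  membership <- matrix(FALSE, n, max(nf, 0L))
  smiles <- character(n)
  for (i in seq_len(n)) {
    rate <- if (labels[i] == 1L) planted$rate_inhibitor else
      planted$rate_noninhibitor
    present <- if (nf > 0L) stats::runif(nf) < rate else logical(0)
    if (nf > 0L) membership[i, ] <- present
    base <- sample(bases, 1L)
    pieces <- c(base, planted$scaffold[present])
    deco <- sample(subs, sample(0:2, 1L), replace = TRUE)
    smiles[i] <- paste0(paste0(pieces, collapse = ""),
                        paste0(deco, collapse = ""))
  }
  out <- data.frame(compound_id = paste0("syn", seq_len(n)),
                    smiles = smiles, label = labels,
                    stringsAsFactors = FALSE)
  if (nf > 0L) {
    mem <- as.data.frame(membership)
    names(mem) <- paste0("has_", seq_len(nf))
    out <- cbind(out, mem)
    attr(out, "fragment_smiles") <- stats::setNames(can, names(mem))
  } else {
    attr(out, "fragment_smiles") <- stats::setNames(character(0), character(0))
  }
  out
}

#' Generate an activity-record fixture table covering every curation branch
#'
#' Emits at least one record per labeling-rule branch (IC50 below/above/in
#' the exclusion window, %inhibition above/below/in its window and at a
#' non-standard concentration, concordant and discrepant replicate sets,
#' all four qualitative outcomes, and a duplicated structure with
#' conflicting labels) together with the expected disposition of each
#' compound. The expected annotations ride alongside the records -- curation
#' itself never sees them.
#'
#' @param seed integer seed (used to shuffle record order).
#' @return list with `records` (ActivityRecord table) and `expected`
#'   (data.frame `compound_id`, `expected`: `"1"`, `"0"`, `"excluded"` or
#'   `"removed"`).
#' @export
gen_activity_records <- function(seed = 1L) {
  # distinct, simple, valid structures so deduplication only fires on purpose
  mols <- c("CCc1ccccc1", "CCCc1ccccc1", "CCCCc1ccccc1", "CCOc1ccccc1",
            "CCNc1ccccc1", "CC(C)c1ccccc1", "CCSc1ccccc1", "CCc1ccncc1",
            "CCc1ccccn1", "CCc1cccs1", "CCOc1ccncc1", "CCCNc1ccccc1",
            "COc1ccccc1C", "CNc1ccccc1C", "CCCOc1ccccc1")
  rec <- function(id, smi, type, value = NA_real_, conc = NA_real_,
                  outcome = NA_character_, source = "synthetic") {
    data.frame(compound_id = id, smiles = smi, index_type = type,
               value = value, concentration = conc, outcome = outcome,
               source_id = source, stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("ic50_low",   mols[1], "IC50", value = 8),            # 1
    rec("ic50_high",  mols[2], "IC50", value = 60),           # 0
    rec("ic50_mid",   mols[3], "IC50", value = 30),           # excluded
    rec("ec50_low",   mols[4], "EC50", value = 2),            # 1
    rec("pct_high",   mols[5], "percent_inhibition", value = 80, conc = 10), # 1
    rec("pct_low",    mols[6], "percent_inhibition", value = 20, conc = 10), # 0
    rec("pct_mid",    mols[7], "percent_inhibition", value = 40, conc = 10), # excluded
    rec("pct_conc",   mols[8], "percent_inhibition", value = 90, conc = 50), # excluded
    rec("rep_conc",   mols[9], "IC50", value = 4),
    rec("rep_conc",   mols[9], "IC50", value = 6),            # mean 5 -> 1
    rec("rep_disc",   mols[10], "IC50", value = 2),
    rec("rep_disc",   mols[10], "IC50", value = 40),          # ratio 20 -> excluded
    rec("qual_act",   mols[11], "qualitative", outcome = "Active"),      # 1
    rec("qual_inact", mols[12], "qualitative", outcome = "Inactive"),    # 0
    rec("qual_inc",   mols[13], "qualitative", outcome = "Inconclusive"),# excluded
    rec("qual_unsp",  mols[14], "qualitative", outcome = "Unspecified"), # excluded
    # same structure, conflicting labels -> both removed at deduplication
    rec("dup_a", mols[15], "IC50", value = 5),
    rec("dup_b", mols[15], "IC50", value = 80)
  )
  expected <- data.frame(
    compound_id = c("ic50_low", "ic50_high", "ic50_mid", "ec50_low",
                    "pct_high", "pct_low", "pct_mid", "pct_conc",
                    "rep_conc", "rep_disc", "qual_act", "qual_inact",
                    "qual_inc", "qual_unsp", "dup_a", "dup_b"),
    expected = c("1", "0", "excluded", "1", "1", "0", "excluded", "excluded",
                 "1", "excluded", "1", "0", "excluded", "excluded",
                 "removed", "removed"),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  records <- records[sample(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, expected = expected)
}
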