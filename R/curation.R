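# Curation: heterogeneous activity records -> deduplicated binary labels.
#
# Labeling rules: IC50/EC50 < 10 uM -> inhibitor (1), > 50 uM -> non-inhibitor
# (0), [10, 50] uM excluded; %inhibition at 10 uM > 50% -> 1, < 25% -> 0,
# [25, 50]% excluded, any other concentration excluded; qualitative outcomes
# Active -> 1, Inactive -> 0, Inconclusive/Unspecified excluded. Boundary
# values fall in the exclusion windows (strict inequalities read literally).

.INDEX_TYPES <- c("IC50", "EC50", "percent_inhibition", "qualitative")

#' Standardize a structure for curation
#'
#' Applies the salt/mixture/metal wash: disconnected counter-ion components
#' without carbon are stripped; a single remaining organic component is kept
#' and canonicalized. True mixtures (two or more carbon-containing
#' components) and metal-organic structures (a non-organic element inside the
#' organic component) are rejected.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `smiles` (input), `canonical_smiles`
#'   (`NA` when rejected) and `reason` (`""`, `"parse"`, `"metal"`,
#'   `"mixture"` or `"inorganic"`).
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- data.frame(smiles = smiles,
                    canonical_smiles = NA_character_,
                    reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(smiles)) {
    res <- .standardize_one(smiles[i])
    out$canonical_smiles[i] <- res$canonical
    out$reason[i] <- res$reason
  }
  out
}

.standardize_one <- function(smi) {
  if (is.na(smi) || !nzchar(trimws(smi))) {
    return(list(canonical = NA_character_, reason = "parse"))
  }
  comps <- strsplit(trimws(smi), ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  parsed <- lapply(comps, .component_elements)
  if (any(vapply(parsed, is.null, logical(1)))) {
    return(list(canonical = NA_character_, reason = "parse"))
  }
  has_c <- vapply(parsed, function(e) "C" %in% e, logical(1))
  if (!any(has_c)) {
    return(list(canonical = NA_character_, reason = "inorganic"))
  }
  if (sum(has_c) > 1L) {
    return(list(canonical = NA_character_, reason = "mixture"))
  }
  organic <- comps[has_c]
  elems <- parsed[[which(has_c)]]
  if (!all(elems %in% .ORGANIC_ELEMENTS)) {
    return(list(canonical = NA_character_, reason = "metal"))
  }
  can <- canonical_smiles(organic)
  if (is.na(can)) return(list(canonical = NA_character_, reason = "parse"))
  list(canonical = can, reason = "")
}

# Element symbols of one SMILES component, or NULL on parse failure.
.component_elements <- function(smi) {
  p <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                error = function(e) NULL)
  if (is.null(p) || length(p) != 1L) return(NULL)
  unique(.atom_symbols(p[[1]]))
}

#' Assign a binary activity label to one activity record
#'
#' Pure decision function implementing the labeling rules (see module header).
#'
#' @param index_type one of `"IC50"`, `"EC50"`, `"percent_inhibition"`,
#'   `"qualitative"`.
#' @param value measured value (uM for IC50/EC50, percent for %inhibition);
#'   ignored for qualitative records.
#' @param concentration assay concentration in uM (required for
#'   %inhibition records; only 10 uM is usable).
#' @param outcome qualitative outcome (`"Active"`, `"Inactive"`,
#'   `"Inconclusive"`, `"Unspecified"`); ignored for quantitative records.
#' @return `1L`, `0L`, or `NA_integer_` (excluded).
#' @export
assign_label <- function(index_type, value = NA_real_,
                         concentration = NA_real_, outcome = NA_character_) {
  if (length(index_type) != 1L || !(index_type %in% .INDEX_TYPES)) {
    stop("unknown index_type: ", paste(index_type, collapse = ", "))
  }
  if (index_type %in% c("IC50", "EC50")) {
    if (is.na(value)) return(NA_integer_)
    if (value <= 0) stop("IC50/EC50 values must be positive")
    if (value < 10) return(1L)
    if (value > 50) return(0L)
    return(NA_integer_)
  }
  if (index_type == "percent_inhibition") {
    if (is.na(value) || is.na(concentration)) return(NA_integer_)
    if (concentration != 10) return(NA_integer_)
    if (value > 50) return(1L)
    if (value < 25) return(0L)
    return(NA_integer_)
  }
  # qualitative
  if (is.na(outcome)) return(NA_integer_)
  switch(outcome,
         Active = 1L,
         Inactive = 0L,
         Inconclusive = NA_integer_,
         Unspecified = NA_integer_,
         NA_integer_)
}

#' Aggregate replicate quantitative measurements of one compound
#'
#' Replicate IC50/EC50 (or %inhibition) values are averaged arithmetically
#' before labeling. If the discrepancy between replicates is significant --
#' operationalized as max/min ratio above `max_ratio` -- the compound is
#' excluded (returns `NA`).
#'
#' @param values replicate measurements (same index type and units).
#' @param max_ratio largest tolerated max/min ratio (default 10).
#' @return the mean value, or `NA_real_` when replicates disagree.
#' @export
aggregate_replicates <- function(values, max_ratio = 10) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  if (length(values) == 1L) return(values)
  if (any(values <= 0)) stop("replicate values must be positive")
  if (max(values) / min(values) > max_ratio) return(NA_real_)
  mean(values)
}

#' Deduplicate labeled compounds by canonical structure
#'
#' Structure-identical entries (same canonical SMILES) collapse to one row;
#' when duplicates carry conflicting labels all copies are removed.
#'
#' @param compounds data.frame with columns `compound_id`,
#'   `canonical_smiles`, `label`.
#' @return deduplicated data.frame; each canonical SMILES appears once.
#' @export
deduplicate <- function(compounds) {
  stopifnot(all(c("compound_id", "canonical_smiles", "label") %in%
                  names(compounds)))
  keep <- integer(0)
  for (smi in unique(compounds$canonical_smiles)) {
    rows <- which(compounds$canonical_smiles == smi)
    if (length(unique(compounds$label[rows])) == 1L) {
      keep <- c(keep, rows[1L])
    }
  }
  out <- compounds[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate an activity-record table into a binary-labeled dataset
#'
#' Full curation pipeline: structures are standardized (salt strip, mixture/
#' metal rejection), records are grouped per compound, replicates of a
#' quantitative index are averaged, and one label per compound is derived
#' with quantitative evidence taking precedence over qualitative outcomes
#' (IC50/EC50 first, then %inhibition, then outcome labels). Finally the
#' labeled set is deduplicated by canonical SMILES, removing structures with
#' incoherent labels.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `index_type`, `value`, `concentration`, `outcome` (missing columns are
#'   filled with `NA`).
#' @param max_ratio replicate-discrepancy threshold, see
#'   [aggregate_replicates()].
#' @return list with `dataset` (data.frame `compound_id`,
#'   `canonical_smiles`, `label`) and `log` (per-compound disposition).
#' @export
curate_dataset <- function(records, max_ratio = 10) {
  for (col in c("value", "concentration")) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  }
  if (is.null(records[["outcome"]])) records[["outcome"]] <- NA_character_
  stopifnot(all(c("compound_id", "smiles", "index_type") %in% names(records)))

  std <- standardize_structure(
    vapply(split(records$smiles, records$compound_id), `[`, character(1), 1L)
  )
  std$compound_id <- names(split(records$smiles, records$compound_id))

  rows <- list()
  log <- list()
  for (i in seq_len(nrow(std))) {
    cid <- std$compound_id[i]
    if (std$reason[i] != "") {
      log[[cid]] <- paste0("rejected:", std$reason[i])
      next
    }
    rec <- records[records$compound_id == cid, , drop = FALSE]
    lab <- .label_compound(rec, max_ratio)
    if (is.na(lab)) {
      log[[cid]] <- "excluded"
      next
    }
    log[[cid]] <- "labeled"
    rows[[cid]] <- data.frame(compound_id = cid,
                              canonical_smiles = std$canonical_smiles[i],
                              label = lab, stringsAsFactors = FALSE)
  }
  labeled <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(), canonical_smiles = character(),
               label = integer())
  rownames(labeled) <- NULL
  dataset <- deduplicate(labeled)
  dup_removed <- setdiff(labeled$compound_id, dataset$compound_id)
  for (cid in dup_removed) log[[cid]] <- "removed:incoherent_duplicate"
  list(dataset = dataset,
       log = data.frame(compound_id = names(log),
                        disposition = unlist(log, use.names = FALSE),
                        stringsAsFactors = FALSE))
}

# One compound's label from its records; quantitative evidence first.
.label_compound <- function(rec, max_ratio) {
  quant <- rec[rec$index_type %in% c("IC50", "EC50"), , drop = FALSE]
  if (nrow(quant) > 0L) {
    avg <- aggregate_replicates(quant$value, max_ratio)
    if (is.na(avg)) return(NA_integer_)
    return(assign_label(quant$index_type[1L], value = avg))
  }
  pct <- rec[rec$index_type == "percent_inhibition", , drop = FALSE]
  pct <- pct[!is.na(pct$concentration) & pct$concentration == 10, , drop = FALSE]
  if (nrow(pct) > 0L) {
    # percent scales may legitimately contain zeros, so the max/min
    # discrepancy rule applies to concentration-response indices only
    avg <- mean(pct$value, na.rm = TRUE)
    if (is.nan(avg)) return(NA_integer_)
    return(assign_label("percent_inhibition", value = avg, concentration = 10))
  }
  qual <- rec[rec$index_type == "qualitative", , drop = FALSE]
  if (nrow(qual) > 0L) {
    labs <- vapply(qual$outcome, function(o)
      assign_label("qualitative", outcome = o), integer(1))
    labs <- labs[!is.na(labs)]
    if (length(unique(labs)) == 1L) return(labs[1L])
  }
  NA_integer_
}
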