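# Internal chemistry helpers shared by curation, featurization and fragments.
# All structure handling goes through ChemmineR/ChemmineOB (OpenBabel).

# Elements regarded as "organic" for curation purposes. Anything else inside a
# carbon-containing component marks the structure as metal-organic.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Strings that fail to parse
#' yield `NA`. Alignment between input and output is kept via molecule titles,
#' so a failed record never shifts the others.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(smiles[idx], " t", seq_along(idx), collapse = "\n")
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))),
    error = function(e) ""
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) != 2L || !grepl("^t[0-9]+$", parts[2L])) next
    j <- as.integer(sub("^t", "", parts[2L]))
    out[idx[j]] <- parts[1L]
  }
  # OpenBabel may abandon a batch at a malformed record; retry the
  # unresolved entries one at a time so one bad SMILES cannot shadow others
  retry <- which(ok & is.na(out))
  for (j in retry) {
    res1 <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste0(smiles[j], "\n"))),
      error = function(e) "")
    val <- strsplit(trimws(res1), "[ \t\n]+")[[1]]
    if (length(val) >= 1L && nzchar(val[1L])) out[j] <- val[1L]
  }
  out
}

# Parse SMILES into an SDFset, dropping (and reporting) invalid entries.
# Returns list(sdf = SDFset, valid = logical vector aligned with input).
.parse_smiles_set <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  can <- canonical_smiles(smiles)
  valid <- !is.na(can)
  sdf <- NULL
  if (any(valid)) {
    smi <- smiles[valid]
    names(smi) <- ids[valid]
    sdf <- ChemmineR::smiles2sdf(smi)
    ChemmineR::cid(sdf) <- ids[valid]
  }
  list(sdf = sdf, valid = valid, canonical = can)
}

# Element symbol per atom from an SDF atom block ("C_1" -> "C").
.atom_symbols <- function(sdf_single) {
  ab <- ChemmineR::atomblock(sdf_single)
  sub("_.*$", "", rownames(ab))
}

# Bond table (a, b, order) of a single SDF, heavy atoms only (smiles2sdf
# output carries no explicit hydrogens).
.bond_table <- function(sdf_single) {
  bb <- ChemmineR::bondblock(sdf_single)
  if (is.null(bb) || nrow(bb) == 0L) {
    return(data.frame(a = integer(), b = integer(), order = integer()))
  }
  data.frame(a = as.integer(bb[, 1L]), b = as.integer(bb[, 2L]),
             order = as.integer(bb[, 3L]))
}

# Molecular graph of a single SDF as an igraph object (vertices = atoms).
.mol_graph <- function(sdf_single) {
  ab <- ChemmineR::atomblock(sdf_single)
  bt <- .bond_table(sdf_single)
  igraph::graph_from_data_frame(
    bt[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(ab)))
  )
}

# Extract an atom subset of a single SDF and return its canonical SMILES.
# Returns NA if extraction or canonicalization fails.
.subset_smiles <- function(sdf_single, atom_rows) {
  frag <- tryCatch(
    ChemmineR::atomsubset(sdf_single, atomrows = sort(unique(atom_rows))),
    error = function(e) NULL
  )
  if (is.null(frag)) return(NA_character_)
  set <- methods::new("SDFset", SDF = list(frag), ID = "frag")
  smi <- tryCatch(
    suppressWarnings(as.character(ChemmineR::sdf2smiles(set))),
    error = function(e) NA_character_
  )
  if (length(smi) != 1L || is.na(smi) || !nzchar(smi)) return(NA_character_)
  canonical_smiles(smi)
}
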