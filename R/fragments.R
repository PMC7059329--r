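# Fragment decomposition (ring / bridge / Bemis-Murcko assemblies) and the
# information-gain + class-frequency enrichment statistics, plus the
# misclassification occurrence-ratio analysis.

#' Decompose a compound into ring-system fragments
#'
#' Three fragment kinds are generated per compound:
#' \describe{
#'   \item{ring_assembly}{a maximal contiguous ring system -- a connected
#'     component of the subgraph induced by ring bonds -- plus any atom
#'     attached to it by a double or triple bond (exocyclic multiple bonds
#'     are retained; single-bond substituents are stripped).}
#'   \item{bridge_assembly}{a ring assembly in which some pair of smallest
#'     rings shares two or more bonds (bridged systems).}
#'   \item{bemis_murcko_assembly}{the molecular scaffold -- everything left
#'     after iteratively pruning terminal atoms -- emitted when it links two
#'     or more ring assemblies.}
#' }
#' Fragments are canonicalized; presence is binary per compound. Acyclic
#' compounds yield an empty set.
#'
#' @param smiles one SMILES string.
#' @return data.frame with columns `fragment` (canonical SMILES) and `kind`;
#'   zero rows for acyclic input.
#' @export
decompose <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  parsed <- .parse_smiles_set(smiles)
  if (!parsed$valid[1L]) stop("invalid structure: ", smiles)
  .decompose_sdf(parsed$sdf[[1]])
}

.decompose_sdf <- function(mol) {
  bt <- .bond_table(mol)
  n_atoms <- nrow(ChemmineR::atomblock(mol))
  empty <- data.frame(fragment = character(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(bt) == 0L) return(empty)
  ring_mask <- .ring_bond_mask(bt, n_atoms)
  if (!any(ring_mask)) return(empty)
  rb <- bt[ring_mask, , drop = FALSE]
  g_ring <- igraph::graph_from_data_frame(
    rb[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms)))
  comp <- igraph::components(g_ring)
  ring_atoms <- which(tabulate(c(rb$a, rb$b), n_atoms) > 0L)
  assemblies <- split(ring_atoms, comp$membership[ring_atoms])
  assemblies <- assemblies[lengths(assemblies) >= 3L]
  out <- list()
  for (atoms in assemblies) {
    atoms_ext <- .with_exocyclic(atoms, bt)
    smi <- .subset_smiles(mol, atoms_ext)
    if (is.na(smi)) next
    out[[length(out) + 1L]] <- data.frame(fragment = smi,
                                          kind = "ring_assembly",
                                          stringsAsFactors = FALSE)
    if (.is_bridged(atoms, rb)) {
      out[[length(out) + 1L]] <- data.frame(fragment = smi,
                                            kind = "bridge_assembly",
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(assemblies) >= 2L) {
    scaffold <- .murcko_atoms(bt, n_atoms)
    if (length(scaffold)) {
      # connected scaffold components containing >= 2 ring assemblies
      g_sc <- igraph::induced_subgraph(
        igraph::graph_from_data_frame(bt[, c("a", "b")], directed = FALSE,
          vertices = data.frame(name = seq_len(n_atoms))),
        scaffold)
      sc_comp <- igraph::components(g_sc)
      for (ci in seq_len(sc_comp$no)) {
        atoms <- as.integer(igraph::V(g_sc)$name[sc_comp$membership == ci])
        n_sys <- length(unique(comp$membership[intersect(atoms, ring_atoms)]))
        if (n_sys < 2L) next
        smi <- .subset_smiles(mol, .with_exocyclic(atoms, bt))
        if (is.na(smi)) next
        out[[length(out) + 1L]] <- data.frame(
          fragment = smi, kind = "bemis_murcko_assembly",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  unique(do.call(rbind, out))
}

# Add atoms attached to `atoms` by a bond of order >= 2.
.with_exocyclic <- function(atoms, bt) {
  multi <- bt[bt$order >= 2L, , drop = FALSE]
  extra <- c(multi$b[multi$a %in% atoms], multi$a[multi$b %in% atoms])
  sort(unique(c(atoms, extra)))
}

# Bridged test: some pair of smallest rings of the assembly shares >= 2 bonds.
# Smallest rings are recovered greedily from the cycle space: all chordless
# cycles up to a size bound, shortest first, keeping rings that cover a not-
# yet-covered ring bond (an SSSR-style basis).
.is_bridged <- function(atoms, rb) {
  sub <- rb[rb$a %in% atoms & rb$b %in% atoms, , drop = FALSE]
  n_cycles <- nrow(sub) - length(atoms) + 1L
  if (n_cycles < 2L) return(FALSE)
  g <- igraph::graph_from_data_frame(sub[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = atoms))
  rings <- .smallest_rings(g, n_cycles)
  if (length(rings) < 2L) return(FALSE)
  edge_sets <- lapply(rings, function(vs) {
    k <- length(vs)
    pairs <- cbind(vs, vs[c(2:k, 1L)])
    apply(pairs, 1, function(e) paste(sort(e), collapse = "-"))
  })
  for (i in seq_along(edge_sets)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(edge_sets[[i]], edge_sets[[j]])) >= 2L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Greedy smallest-ring basis of a ring-bond graph (vertex-name cycles).
.smallest_rings <- function(g, n_cycles) {
  # candidate cycles: for each edge (u, v), shortest cycle through it =
  # u-v edge + shortest u-v path avoiding that edge
  el <- igraph::as_edgelist(g, names = FALSE)
  cand <- list()
  for (e in seq_len(nrow(el))) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = el[e, 1L], to = el[e, 2L], output = "vpath"))
    path <- sp$vpath[[1L]]
    if (length(path) < 3L) next
    cand[[length(cand) + 1L]] <- as.integer(igraph::V(g)$name[as.integer(path)])
  }
  if (!length(cand)) return(list())
  cand <- cand[order(lengths(cand))]
  chosen <- list()
  covered <- character(0)
  for (cyc in cand) {
    k <- length(cyc)
    edges <- apply(cbind(cyc, cyc[c(2:k, 1L)]), 1,
                   function(e) paste(sort(e), collapse = "-"))
    key <- paste(sort(edges), collapse = "|")
    if (key %in% vapply(chosen, attr, character(1), "key")) next
    if (all(edges %in% covered) || length(chosen) >= n_cycles) next
    attr(cyc, "key") <- key
    chosen[[length(chosen) + 1L]] <- cyc
    covered <- union(covered, edges)
  }
  chosen
}

# Iterative leaf pruning: atoms of the Murcko scaffold (rings + linkers).
.murcko_atoms <- function(bt, n_atoms) {
  adj <- lapply(seq_len(n_atoms), function(i)
    c(bt$b[bt$a == i], bt$a[bt$b == i]))
  alive <- rep(TRUE, n_atoms)
  repeat {
    deg <- vapply(seq_len(n_atoms), function(i)
      if (alive[i]) sum(alive[adj[[i]]]) else 0L, integer(1))
    leaves <- alive & deg <= 1L
    if (!any(leaves)) break
    alive[leaves] <- FALSE
  }
  which(alive)
}

#' Class frequency of a fragment (enrichment ratio)
#'
#' `F = (N_fragment_class * N_total) / (N_fragment_total * N_class)`:
#' a value above 1 means the fragment is enriched in that class.
#'
#' @param count_in_class compounds of the class containing the fragment.
#' @param class_size number of compounds in the class.
#' @param fragment_total_count compounds (both classes) containing the
#'   fragment; must be positive.
#' @param dataset_total total number of compounds.
#' @return the class frequency (non-negative).
#' @export
class_frequency <- function(count_in_class, class_size,
                            fragment_total_count, dataset_total) {
  if (fragment_total_count == 0) stop("fragment_total_count must be positive")
  stopifnot(count_in_class <= fragment_total_count,
            fragment_total_count <= dataset_total,
            count_in_class <= class_size)
  (count_in_class * dataset_total) / (fragment_total_count * class_size)
}

#' Information gain of a fragment (bits)
#'
#' Reduction in class entropy obtained by conditioning on fragment
#' presence/absence: `IG = Ent(D) - sum_v (N_v / N) * Ent(D_v)` with base-2
#' entropy `Ent = -sum_k p_k log2 p_k` and the convention `0 * log2(0) = 0`.
#'
#' @param count_inhibitor,count_noninhibitor compounds of each class
#'   containing the fragment.
#' @param n_inhibitors,n_noninhibitors class sizes.
#' @return information gain in bits, in `[0, Ent(D)]`.
#' @export
information_gain <- function(count_inhibitor, count_noninhibitor,
                             n_inhibitors, n_noninhibitors) {
  stopifnot(count_inhibitor <= n_inhibitors,
            count_noninhibitor <= n_noninhibitors)
  n <- n_inhibitors + n_noninhibitors
  if (n == 0) stop("both classes empty")
  ent <- function(a, b) {
    tot <- a + b
    if (tot == 0) return(0)
    p <- c(a, b) / tot
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  present <- count_inhibitor + count_noninhibitor
  absent <- n - present
  ent(n_inhibitors, n_noninhibitors) -
    (present / n) * ent(count_inhibitor, count_noninhibitor) -
    (absent / n) * ent(n_inhibitors - count_inhibitor,
                       n_noninhibitors - count_noninhibitor)
}

#' Fragment enrichment table for a labeled compound library
#'
#' Decomposes every compound, merges records by canonical (fragment, kind),
#' counts the number of compounds of each class containing each fragment
#' (binary presence, not multiplicity), and populates class frequencies F1
#' (inhibitors) / F2 (non-inhibitors) and information gain. Sorted by IG
#' descending.
#'
#' @param compounds data.frame with `smiles` (or `canonical_smiles`) and
#'   `label`, or character SMILES vector with `labels` supplied.
#' @param labels 0/1 labels when `compounds` is a character vector.
#' @return data.frame of `FragmentRecord`s: `fragment`, `kind`,
#'   `count_inhibitor`, `count_noninhibitor`, `F1`, `F2`, `IG`.
#' @export
fragment_table <- function(compounds, labels = NULL) {
  if (is.character(compounds)) {
    compounds <- data.frame(smiles = compounds, label = labels,
                            stringsAsFactors = FALSE)
  }
  smi_col <- if (!is.null(compounds$canonical_smiles)) "canonical_smiles"
    else "smiles"
  stopifnot(!is.null(compounds$label))
  .check_binary(compounds$label)
  n1 <- sum(compounds$label == 1L)
  n0 <- sum(compounds$label == 0L)
  parsed <- .parse_smiles_set(compounds[[smi_col]])
  frags <- list()
  valid_ix <- which(parsed$valid)
  for (j in seq_along(valid_ix)) {
    i <- valid_ix[j]
    d <- .decompose_sdf(parsed$sdf[[j]])
    if (nrow(d) == 0L) next
    d$label <- compounds$label[i]
    frags[[length(frags) + 1L]] <- d
  }
  if (!length(frags)) {
    return(data.frame(fragment = character(), kind = character(),
                      count_inhibitor = integer(),
                      count_noninhibitor = integer(),
                      F1 = numeric(), F2 = numeric(), IG = numeric()))
  }
  all_f <- do.call(rbind, frags)
  key <- paste(all_f$fragment, all_f$kind, sep = "\r")
  c1 <- tapply(all_f$label == 1L, key, sum)
  c0 <- tapply(all_f$label == 0L, key, sum)
  parts <- do.call(rbind, strsplit(names(c1), "\r", fixed = TRUE))
  out <- data.frame(fragment = parts[, 1L], kind = parts[, 2L],
                    count_inhibitor = as.integer(c1),
                    count_noninhibitor = as.integer(c0),
                    stringsAsFactors = FALSE)
  tot <- out$count_inhibitor + out$count_noninhibitor
  out$F1 <- mapply(class_frequency, out$count_inhibitor, n1, tot, n1 + n0)
  out$F2 <- mapply(class_frequency, out$count_noninhibitor, n0, tot, n1 + n0)
  out$IG <- mapply(information_gain, out$count_inhibitor,
                   out$count_noninhibitor, n1, n0)
  out <- out[order(-out$IG, out$fragment), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_sizes") <- c(inhibitors = n1, noninhibitors = n0)
  out
}

#' Rank fragments into inhibitor- and non-inhibitor-associated lists
#'
#' Fragments more frequent in inhibitors (`F1 > F2`) form the positive
#' list, those more frequent in non-inhibitors (`F2 > F1`) the negative
#' list; ties (`F1 == F2`) belong to neither. Each list is sorted by IG
#' descending and truncated to `top_n`.
#'
#' @param table a [fragment_table()].
#' @param top_n rows per list (default 10).
#' @return list with data.frames `positive` and `negative`.
#' @export
rank_fragments <- function(table, top_n = 10L) {
  pos <- table[table$F1 > table$F2, , drop = FALSE]
  neg <- table[table$F2 > table$F1, , drop = FALSE]
  pos <- utils::head(pos[order(-pos$IG), , drop = FALSE], top_n)
  neg <- utils::head(neg[order(-neg$IG), , drop = FALSE], top_n)
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}

#' Fragment occurrence ratios in training, test and misclassified sets
#'
#' Decomposes the three sets, keeps fragments whose count in the
#' misclassified set is at least `min_count` (default 2), and reports the
#' occurrence ratio `100 * count / set size` per set.
#'
#' @param train_smiles,test_smiles,misclassified_smiles SMILES vectors; the
#'   misclassified set should be a subset of the test set.
#' @param min_count minimum misclassified-set count (default 2).
#' @return data.frame with per-set counts and occurrence ratios (percent).
#' @export
misclassification_enrichment <- function(train_smiles, test_smiles,
                                         misclassified_smiles,
                                         min_count = 2L) {
  if (length(misclassified_smiles) == 0L) {
    return(data.frame(fragment = character(), kind = character(),
                      count_train = integer(), count_test = integer(),
                      count_misclassified = integer(),
                      or_train = numeric(), or_test = numeric(),
                      or_misclassified = numeric()))
  }
  count_set <- function(smiles) {
    parsed <- .parse_smiles_set(smiles)
    keys <- character(0)
    for (j in seq_len(sum(parsed$valid))) {
      d <- .decompose_sdf(parsed$sdf[[j]])
      if (nrow(d)) keys <- c(keys, paste(d$fragment, d$kind, sep = "\r"))
    }
    table(keys)
  }
  mis <- count_set(misclassified_smiles)
  mis <- mis[mis >= min_count]
  if (length(mis) == 0L) {
    return(misclassification_enrichment(train_smiles, test_smiles,
                                        character(0)))
  }
  tr <- count_set(train_smiles)
  te <- count_set(test_smiles)
  keys <- names(mis)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  get <- function(tab, k) ifelse(k %in% names(tab), as.integer(tab[k]), 0L)
  ct <- vapply(keys, function(k) get(tr, k), integer(1))
  ce <- vapply(keys, function(k) get(te, k), integer(1))
  cm <- as.integer(mis)
  out <- data.frame(
    fragment = parts[, 1L], kind = parts[, 2L],
    count_train = ct, count_test = ce, count_misclassified = cm,
    or_train = 100 * ct / length(train_smiles),
    or_test = 100 * ce / length(test_smiles),
    or_misclassified = 100 * cm / length(misclassified_smiles),
    stringsAsFactors = FALSE)
  out <- out[order(-out$count_misclassified), , drop = FALSE]
  rownames(out) <- NULL
  out
}
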