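# ---------------------------------------------------------------------------
# ECFP6 fingerprints, Tanimoto distances, neighbor graph and coverage
# ---------------------------------------------------------------------------

#' ECFP6 circular fingerprints
#'
#' Hashed extended-connectivity fingerprints of diameter 6 bonds (radius 3),
#' computed by OpenBabel and folded (bitwise OR) from its native 4096-bit form
#' to `nbits`. Deterministic: any SMILES spelling of the same molecule gives
#' the same bits.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits fingerprint length; must divide 4096 (default 2048).
#' @return integer 0/1 matrix, one row per molecule, `nbits` columns.
#' @export
ecfp6 <- function(smiles, nbits = 2048) {
  stopifnot(length(smiles) >= 1, nbits >= 1, 4096 %% nbits == 0)
  can <- canonical_smiles(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  }
  raw <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", paste(can, collapse = "\n"), identity),
    "ECFP6"
  )
  raw <- matrix(as.integer(raw), nrow = length(can))
  if (nbits == 4096L) return(raw)
  folds <- 4096L %/% nbits
  out <- matrix(0L, nrow = nrow(raw), ncol = nbits)
  for (k in seq_len(folds)) {
    blk <- raw[, ((k - 1L) * nbits + 1L):(k * nbits), drop = FALSE]
    out <- pmax(out, blk)
  }
  out
}

#' Tanimoto distance between two fingerprints
#'
#' `d = 1 - |a & b| / |a | b|`. Symmetric, zero for identical bit sets, one
#' for disjoint nonempty sets. Two empty fingerprints are defined as
#' identical (`d = 0`), with a message.
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return distance in \[0, 1\].
#' @export
tanimoto_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    message("both fingerprints empty; distance defined as 0")
    return(0)
  }
  1 - inter / uni
}

# Dense pairwise Tanimoto distance matrix from a 0/1 fingerprint matrix.
.tanimoto_matrix <- function(fp) {
  fp <- matrix(as.numeric(fp > 0), nrow = nrow(fp))
  inter <- tcrossprod(fp)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # pairs of empty fingerprints are identical by convention
  diag(d) <- 0
  d
}

#' Construct a molecular space from fingerprints
#'
#' Builds the container over which coverage and selection are defined: the
#' molecules, their pairwise Tanimoto distances, and the neighbor relation
#' `{j : d_ij < d_th}` (strict inequality; every molecule is its own neighbor
#' whenever `d_th > 0` since `d_ii = 0`).
#'
#' @param fp integer 0/1 fingerprint matrix (rows = molecules).
#' @param d_th Tanimoto distance threshold in \[0, 1\] (default 0.3).
#' @param molecules optional molecule table aligned with `fp` rows.
#' @param weights per-molecule coverage weights (default 1 for all, so the
#'   total weight equals the number of molecules).
#' @return an object of class `mol_space`.
#' @export
molspace <- function(fp, d_th = 0.3, molecules = NULL, weights = NULL) {
  stopifnot(is.matrix(fp), nrow(fp) >= 1, d_th >= 0, d_th <= 1)
  molspace_from_distances(.tanimoto_matrix(fp), d_th = d_th,
                          molecules = molecules, weights = weights, fp = fp)
}

#' Construct a molecular space from a precomputed distance matrix
#'
#' Useful for toy graphs and custom metrics; [molspace()] is the fingerprint
#' front end.
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param d_th neighbor threshold (strict `<`).
#' @param molecules optional molecule table.
#' @param weights per-molecule weights (default all 1).
#' @param fp optional fingerprint matrix to retain.
#' @return an object of class `mol_space`.
#' @export
molspace_from_distances <- function(dist, d_th = 0.3, molecules = NULL,
                                    weights = NULL, fp = NULL) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist),
            d_th >= 0, d_th <= 1)
  if (max(abs(dist - t(dist))) > 1e-12) stop("distance matrix not symmetric")
  n <- nrow(dist)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  nb <- lapply(seq_len(n), function(i) which(dist[i, ] < d_th))
  ids <- if (!is.null(molecules) && !is.null(molecules$id)) {
    as.character(molecules$id)
  } else {
    sprintf("m%04d", seq_len(n))
  }
  # deterministic tie order for argmax selections: canonical-SMILES
  # lexicographic where available, else index order
  tie_rank <- if (!is.null(molecules) && !is.null(molecules$smiles)) {
    rank(molecules$smiles, ties.method = "first")
  } else {
    seq_len(n)
  }
  structure(
    list(nmol = n, d_th = d_th, dist = dist, fp = fp, nb = nb,
         ids = ids, molecules = molecules, weights = weights,
         w_tot = sum(weights), tie_rank = tie_rank),
    class = "mol_space"
  )
}

#' @export
print.mol_space <- function(x, ...) {
  cat("<mol_space> ", x$nmol, " molecules, d_th = ", x$d_th,
      ", total weight = ", x$w_tot, "\n", sep = "")
  deg <- lengths(x$nb)
  cat("  neighbors per molecule (incl. self): median ", median(deg),
      ", max ", max(deg), "\n", sep = "")
  invisible(x)
}

#' Merge accessible and generated molecules into one space
#'
#' Union with duplicates merged by canonical SMILES; when a structure appears
#' in both lists the accessible record wins. Fingerprints are computed for the
#' merged set.
#'
#' @param accessible,generated molecule tables (canonical SMILES).
#' @param d_th neighbor threshold (default 0.3).
#' @param nbits fingerprint length (default 2048).
#' @return a `mol_space` whose `molecules` table carries roles and provenance.
#' @export
build_molspace <- function(accessible, generated, d_th = 0.3, nbits = 2048) {
  cols <- c("id", "smiles", "role", "mw", "core_id", "substituent_id",
            "reaction_id")
  merged <- rbind(accessible[, cols, drop = FALSE],
                  generated[, cols, drop = FALSE])
  if (!nrow(merged)) stop("empty union of accessible and generated")
  merged <- merged[!duplicated(merged$smiles), , drop = FALSE]
  rownames(merged) <- NULL
  molspace(ecfp6(merged$smiles, nbits = nbits), d_th = d_th,
           molecules = merged)
}

#' Neighbors of a molecule within a subset
#'
#' The cover relation: `C_subset(m_i) = {j in subset : d_ij < d_th}` (strict).
#'
#' @param space a `mol_space`.
#' @param i molecule index.
#' @param subset index set to intersect with (default: the whole space).
#' @return sorted integer vector of neighbor indices.
#' @export
neighbors <- function(space, i, subset = seq_len(space$nmol)) {
  stopifnot(inherits(space, "mol_space"), i >= 1, i <= space$nmol)
  intersect(space$nb[[i]], subset)
}

# Covered index set for a selection: union of neighborhoods, expanded once
# more through the neighbor relation for order 2.
.covered_set <- function(space, selected, order = 1) {
  cov <- rep(FALSE, space$nmol)
  for (i in selected) cov[space$nb[[i]]] <- TRUE
  if (order == 2) {
    cov2 <- cov
    for (i in which(cov)) cov2[space$nb[[i]]] <- TRUE
    cov <- cov2
  }
  cov
}

#' Coverage of the space by a selection
#'
#' Weighted fraction of the space lying within the distance threshold of any
#' selected molecule (`order = 1`), optionally expanded once more through the
#' neighbor relation (`order = 2`, "neighbors of neighbors"). Equals
#' `f_cov(selected) / W_tot`.
#'
#' @param space a `mol_space`.
#' @param selected integer vector of selected molecule indices (may be empty).
#' @param order 1 or 2.
#' @return coverage fraction in \[0, 1\].
#' @export
coverage <- function(space, selected, order = 1) {
  stopifnot(inherits(space, "mol_space"), order %in% c(1, 2))
  if (!length(selected)) return(0)
  stopifnot(all(selected >= 1), all(selected <= space$nmol))
  sum(space$weights[.covered_set(space, selected, order)]) / space$w_tot
}

#' Dump the neighbor graph as an edge table
#'
#' @param space a `mol_space`.
#' @return data.frame with columns `i`, `j`, `d_ij` for all ordered pairs with
#'   `d_ij < d_th` and `i < j`.
#' @export
neighbor_edges <- function(space) {
  stopifnot(inherits(space, "mol_space"))
  rows <- list()
  for (i in seq_len(space$nmol)) {
    js <- space$nb[[i]]
    js <- js[js > i]
    if (length(js)) {
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = js, d_ij = space$dist[i, js])
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(0), j = integer(0), d_ij = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
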