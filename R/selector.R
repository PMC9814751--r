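# ---------------------------------------------------------------------------
# Molecule prioritization: greedy submodular cover maximization with an
# evaluated-neighborhood penalty, plus random and GP-uncertainty baselines
# ---------------------------------------------------------------------------

#' Selection state for greedy prioritization
#'
#' Tracks the ordered evaluated list, the covered/uncovered partition of the
#' space, and the per-molecule penalty weights (1 on evaluated molecules,
#' 0 elsewhere by default).
#'
#' @param space a `mol_space`.
#' @param evaluated integer vector of already-evaluated molecule indices,
#'   in evaluation order.
#' @return list with elements `evaluated`, `covered` (logical), `penalty`
#'   (numeric per molecule).
#' @export
selection_state <- function(space, evaluated = integer(0)) {
  stopifnot(inherits(space, "mol_space"))
  covered <- .covered_set(space, evaluated, order = 1)
  penalty <- numeric(space$nmol)
  penalty[evaluated] <- 1
  list(evaluated = as.integer(evaluated), covered = covered,
       penalty = penalty)
}

#' Marginal selection score of a candidate molecule
#'
#' The greedy objective for the next pick: the weighted count of still-
#' uncovered molecules the candidate would newly cover, minus
#' `lam * W_tot` times the penalty mass in its neighborhood. With unit
#' weights, unit penalties on evaluated molecules and `lam = 1` this is
#' `Count({j uncovered : d_ij < d_th}) - NMOL * Count({j evaluated : d_ij < d_th})`.
#'
#' @param space a `mol_space`.
#' @param state a [selection_state()].
#' @param i candidate index (must not be evaluated already).
#' @param lam penalty balance in \[0, 1\] (default 1: maximal penalty).
#' @return signed numeric score.
#' @export
sfmmol_score <- function(space, state, i, lam = 1) {
  stopifnot(!(i %in% state$evaluated), lam >= 0, lam <= 1)
  nb_i <- space$nb[[i]]
  gain <- sum(space$weights[nb_i[!state$covered[nb_i]]])
  pen <- lam * space$w_tot * sum(state$penalty[nb_i])
  gain - pen
}

.new_ranking <- function(order, scores, algorithm, space, seed = NA_integer_) {
  structure(
    list(order = as.integer(order), ids = space$ids[order],
         scores = as.numeric(scores), algorithm = algorithm, seed = seed),
    class = "mol_ranking"
  )
}

#' @export
print.mol_ranking <- function(x, ...) {
  cat("<mol_ranking> ", x$algorithm, ", ", length(x$order),
      " molecules\n", sep = "")
  cat("  head: ", paste(head(x$ids, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# argmax with the deterministic tie rule (lowest tie_rank wins)
.argmax_tie <- function(scores, candidates, tie_rank) {
  best <- candidates[scores == max(scores)]
  best[which.min(tie_rank[best])]
}

#' Greedy submodular prioritization of a molecular space
#'
#' Iteratively picks the candidate maximizing [sfmmol_score()], then marks the
#' pick as evaluated and its neighborhood as covered. Deterministic: ties are
#' broken by canonical-SMILES lexicographic order (index order for spaces
#' without SMILES). Stops at `n_select` picks or when every molecule has been
#' evaluated.
#'
#' @param space a `mol_space`.
#' @param n_select ranking length (truncated to the space size with a
#'   warning if larger).
#' @param lam penalty balance in \[0, 1\] (default 1).
#' @return a `mol_ranking` with the marginal score at each pick.
#' @export
rank_sfmmol <- function(space, n_select = 1000, lam = 1) {
  stopifnot(inherits(space, "mol_space"), n_select >= 1)
  if (n_select > space$nmol) {
    warning("n_select exceeds space size; truncated to ", space$nmol)
    n_select <- space$nmol
  }
  state <- selection_state(space)
  order <- integer(n_select)
  scores <- numeric(n_select)
  for (step in seq_len(n_select)) {
    cand <- setdiff(seq_len(space$nmol), state$evaluated)
    s <- vapply(cand, function(i) sfmmol_score(space, state, i, lam),
                numeric(1))
    pick <- .argmax_tie(s, cand, space$tie_rank)
    order[step] <- pick
    scores[step] <- s[match(pick, cand)]
    state$evaluated <- c(state$evaluated, pick)
    state$covered[space$nb[[pick]]] <- TRUE
    state$penalty[pick] <- 1
  }
  .new_ranking(order, scores, "sfmmol", space)
}

#' Random prioritization baseline
#'
#' A uniform random permutation prefix, reproducible per seed.
#'
#' @param space a `mol_space`.
#' @param n_select ranking length.
#' @param seed RNG seed.
#' @return a `mol_ranking` (scores are the uniform draws, sorted descending).
#' @export
rank_random <- function(space, n_select = space$nmol, seed = 0) {
  stopifnot(inherits(space, "mol_space"), n_select >= 1)
  n_select <- min(n_select, space$nmol)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- runif(space$nmol)
  ord <- order(u, decreasing = TRUE)[seq_len(n_select)]
  .new_ranking(ord, u[ord], "random", space, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Gaussian-process posterior variances over candidates
#'
#' Posterior predictive variance of a GP with Tanimoto-similarity kernel
#' `K = 1 - d`, unit prior variance and jitter on the evaluated block. The
#' variance depends only on the evaluated inputs, never on response values.
#'
#' @param space a `mol_space`.
#' @param evaluated indices of evaluated molecules (nonempty).
#' @param candidates indices to score (default: all non-evaluated).
#' @param jitter diagonal regularization (default 1e-8).
#' @return named numeric vector of variances for `candidates`.
#' @export
gp_posterior_variance <- function(space, evaluated,
                                  candidates = setdiff(seq_len(space$nmol),
                                                       evaluated),
                                  jitter = 1e-8) {
  stopifnot(inherits(space, "mol_space"), length(evaluated) >= 1)
  if (space$nmol > 1 && max(space$dist) == 0) {
    stop("degenerate kernel: all fingerprints identical")
  }
  K <- 1 - space$dist
  Kee <- K[evaluated, evaluated, drop = FALSE] +
    diag(jitter, length(evaluated))
  # Tanimoto similarity of genuine fingerprints is positive semi-definite, but
  # user-supplied distance matrices need not be; clip negative eigenvalues in
  # the evaluated block if plain Cholesky fails.
  R <- tryCatch(chol(Kee), error = function(e) NULL)
  if (is.null(R)) {
    eg <- eigen(Kee, symmetric = TRUE)
    Kee <- eg$vectors %*% (pmax(eg$values, jitter) * t(eg$vectors))
    R <- chol(Kee)
  }
  Kec <- K[evaluated, candidates, drop = FALSE]
  a <- backsolve(R, Kec, transpose = TRUE)
  v <- 1 - colSums(a^2)
  setNames(pmax(v, 0), space$ids[candidates])
}

#' Uncertainty-sampling baseline (GP least-confident selection)
#'
#' At each step, fits a Gaussian-process posterior on the evaluated molecules
#' (Tanimoto-similarity kernel, unit prior variance, no hyperparameter
#' optimization) and picks the candidate with maximal posterior variance. The
#' first pick, where no posterior exists, is the molecule with the largest
#' summed distance to all others. Deterministic.
#'
#' @param space a `mol_space`.
#' @param n_select ranking length.
#' @param jitter kernel regularization (default 1e-8).
#' @return a `mol_ranking` (scores are the posterior variances at each pick).
#' @export
rank_unc <- function(space, n_select = space$nmol, jitter = 1e-8) {
  stopifnot(inherits(space, "mol_space"), n_select >= 1)
  n_select <- min(n_select, space$nmol)
  if (space$nmol > 1 && max(space$dist) == 0) {
    stop("degenerate kernel: all fingerprints identical")
  }
  sums <- rowSums(space$dist)
  first <- .argmax_tie(sums, seq_len(space$nmol), space$tie_rank)
  order <- integer(n_select)
  scores <- numeric(n_select)
  order[1] <- first
  scores[1] <- 1
  for (step in seq_len(n_select)[-1]) {
    evaluated <- order[seq_len(step - 1)]
    cand <- setdiff(seq_len(space$nmol), evaluated)
    v <- gp_posterior_variance(space, evaluated, cand, jitter = jitter)
    pick <- .argmax_tie(as.numeric(v), cand, space$tie_rank)
    order[step] <- pick
    scores[step] <- v[match(pick, cand)]
  }
  .new_ranking(order, scores, "unc", space)
}

#' Accumulated coverage along a ranking
#'
#' Coverage of the space after each prefix of the ranking, starting from the
#' empty prefix (coverage 0). Nondecreasing by construction.
#'
#' @param space a `mol_space`.
#' @param ranking a `mol_ranking` over `space` (or an integer index vector).
#' @param order neighbor order, 1 or 2 (default 2, the benchmark convention).
#' @return data.frame with columns `n_evaluated` (0..length) and `coverage`.
#' @export
coverage_curve <- function(space, ranking, order = 2) {
  stopifnot(inherits(space, "mol_space"), order %in% c(1, 2))
  picks <- if (inherits(ranking, "mol_ranking")) ranking$order else
    as.integer(ranking)
  cov1 <- rep(FALSE, space$nmol)
  cov2 <- rep(FALSE, space$nmol)
  out <- numeric(length(picks) + 1L)
  for (k in seq_along(picks)) {
    newly <- space$nb[[picks[k]]]
    newly <- newly[!cov1[newly]]
    cov1[newly] <- TRUE
    if (order == 2) {
      for (j in newly) cov2[space$nb[[j]]] <- TRUE
    }
    cov <- if (order == 2) cov2 else cov1
    out[k + 1L] <- sum(space$weights[cov]) / space$w_tot
  }
  data.frame(n_evaluated = 0:length(picks), coverage = out)
}
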