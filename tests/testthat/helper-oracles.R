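# Shared fixtures and independent oracles (built on the raw distance matrix
# only, never on the package's neighbor lists or selection state).

# 6-molecule path graph: adjacent distance 0.2, everything else 0.9
path_space <- function(d_th = 0.3) {
  D <- matrix(0.9, 6, 6)
  diag(D) <- 0
  for (i in 1:5) {
    D[i, i + 1] <- 0.2
    D[i + 1, i] <- 0.2
  }
  molspace_from_distances(D, d_th = d_th)
}

# brute-force covered set from the distance matrix
oracle_covered <- function(D, selected, d_th, order = 1) {
  n <- nrow(D)
  cov <- rep(FALSE, n)
  for (i in selected) cov <- cov | (D[i, ] < d_th)
  if (order == 2) {
    cov2 <- cov
    for (i in which(cov)) cov2 <- cov2 | (D[i, ] < d_th)
    cov <- cov2
  }
  cov
}

oracle_coverage <- function(D, selected, d_th, order = 1, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(D))
  if (!length(selected)) return(0)
  sum(weights[oracle_covered(D, selected, d_th, order)]) / sum(weights)
}

# exhaustive marginal score: uncovered neighbors minus NMOL * evaluated
# neighbors, straight from the definition
oracle_score <- function(D, evaluated, i, d_th) {
  n <- nrow(D)
  covered <- oracle_covered(D, evaluated, d_th, order = 1)
  sum(D[i, ] < d_th & !covered) - n * sum(D[i, evaluated] < d_th)
}

# full greedy reference: at each step take the exhaustive argmax with
# lowest-index tie-breaking
oracle_greedy <- function(D, d_th, n_select) {
  n <- nrow(D)
  evaluated <- integer(0)
  for (step in seq_len(n_select)) {
    cand <- setdiff(seq_len(n), evaluated)
    s <- vapply(cand, function(i) oracle_score(D, evaluated, i, d_th),
                numeric(1))
    evaluated <- c(evaluated, cand[which.max(s)])
  }
  evaluated
}
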