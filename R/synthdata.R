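# ---------------------------------------------------------------------------
# Synthetic-data generators with known ground truth: clustered fingerprint
# spaces, Gaussian-peaked spectra, labeled molecule-solvent tables
# ---------------------------------------------------------------------------

#' Synthetic clustered fingerprint space
#'
#' Emulates the cluster structure of a real chemical space without any
#' chemistry: each cluster has a random prototype bit set (each bit on with
#' probability `proto_density`), and members are copies of their prototype
#' with independent bit flips. The planted assignment is returned for oracle
#' checks. With the defaults (`proto_density = 0.5`), within-cluster Tanimoto
#' distances concentrate well below between-cluster distances (~2/3), so a
#' threshold of 0.3 separates the planted clusters.
#'
#' @param n_molecules number of molecules.
#' @param n_clusters number of planted clusters (members assigned uniformly).
#' @param nbits fingerprint length (default 256).
#' @param flip per-bit flip probability within a cluster, in \[0, 0.5).
#' @param d_th neighbor threshold of the returned space (default 0.3).
#' @param seed RNG seed.
#' @param prototypes optional 0/1 matrix (`n_clusters` x `nbits`) of
#'   prototype bit sets, overriding the random prototypes.
#' @param proto_density prototype bit density (default 0.5).
#' @return a `mol_space`; attribute `"true_clusters"` holds the planted
#'   assignment (integer vector).
#' @export
synth_space <- function(n_molecules, n_clusters, nbits = 256, flip = 0.05,
                        d_th = 0.3, seed = 0, prototypes = NULL,
                        proto_density = 0.5) {
  stopifnot(n_clusters >= 1, n_clusters <= n_molecules,
            flip >= 0, flip < 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(prototypes)) {
    prototypes <- matrix(
      as.integer(runif(n_clusters * nbits) < proto_density),
      nrow = n_clusters
    )
  } else {
    stopifnot(nrow(prototypes) == n_clusters, ncol(prototypes) == nbits)
  }
  assign <- sample(rep_len(seq_len(n_clusters), n_molecules))
  fp <- prototypes[assign, , drop = FALSE]
  if (flip > 0) {
    flips <- matrix(runif(n_molecules * nbits) < flip, nrow = n_molecules)
    fp <- abs(fp - as.integer(flips))
  }
  mols <- data.frame(id = sprintf("syn%04d", seq_len(n_molecules)),
                     cluster = assign, stringsAsFactors = FALSE)
  sp <- molspace(fp, d_th = d_th, molecules = mols)
  attr(sp, "true_clusters") <- assign
  sp
}

#' Synthetic Gaussian-peaked spectrum with analytic ground truth
#'
#' A sum of Gaussian components (main peak plus optional shorter-wavelength
#' shoulders, emulating a Soret band with aggregate shoulder) with iid
#' Gaussian noise. The ground truth records the main component's analytic
#' indicators (`area = height * fwhm * sqrt(pi / (4 ln 2))`); with zero
#' components the truth is "no peak".
#'
#' @param components data.frame with columns `center` (nm), `height`,
#'   `fwhm` (nm); the highest component is the main peak. May have 0 rows.
#' @param noise_sd absorbance noise standard deviation (default 0).
#' @param grid wavelength grid (default 350-550 nm by 0.5).
#' @param seed RNG seed for the noise.
#' @return list with `spectrum` (data.frame `wavelength`, `absorbance`) and
#'   `truth` (list: `peak_found`, `lambda_max`, `intensity`, `fwhm`, `area`).
#' @export
synth_spectrum <- function(components, noise_sd = 0,
                           grid = seq(350, 550, by = 0.5), seed = 0) {
  stopifnot(is.data.frame(components),
            all(c("center", "height", "fwhm") %in% names(components)) ||
              nrow(components) == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  y <- numeric(length(grid))
  for (r in seq_len(nrow(components))) {
    y <- y + gauss_peak(grid, components$height[r], components$center[r],
                        components$fwhm[r])
  }
  if (noise_sd > 0) y <- y + rnorm(length(grid), sd = noise_sd)
  truth <- if (nrow(components) == 0) {
    list(peak_found = FALSE, lambda_max = NA_real_, intensity = NA_real_,
         fwhm = NA_real_, area = NA_real_)
  } else {
    main <- which.max(components$height)
    list(peak_found = TRUE,
         lambda_max = components$center[main],
         intensity = components$height[main],
         fwhm = components$fwhm[main],
         area = components$height[main] * components$fwhm[main] *
           .GAUSS_AREA_C)
  }
  list(spectrum = data.frame(wavelength = grid, absorbance = y),
       truth = truth)
}

#' Synthetic molecule-solvent evaluation table with a planted rule
#'
#' Generates a labeled dataset whose structure-solubility rule is known:
#' pair features are the molecule fingerprint concatenated with a random
#' solvent fingerprint; a linear rule score is squashed to \[0, 1\] and used
#' monotonically as both relative indicators; categories 0-4 come from fixed
#' score thresholds (0.2, 0.4, 0.6, 0.8); the good-solvent label (category 3
#' or 4) is flipped with probability `noise`.
#'
#' @param space a `mol_space` with fingerprints (e.g. from [synth_space()]).
#' @param n_solvents number of synthetic solvents (default 16).
#' @param rule numeric weight vector of length `ncol(fp) + nbits_solvent`;
#'   default: sparse random weights (10% nonzero, standard normal).
#' @param noise label-flip probability (default 0).
#' @param nbits_solvent solvent fingerprint length (default 16).
#' @param seed RNG seed.
#' @return list with `table` (data.frame: `molecule_id`, `solvent_id`,
#'   `peak_found`, `fwhm_r`, `area_r`, `category`, `label_good`), `features`
#'   (numeric matrix aligned with rows) and `truth` (list: `rule`, `score`,
#'   `label_true`).
#' @export
synth_solubility_table <- function(space, n_solvents = 16, rule = NULL,
                                   noise = 0, nbits_solvent = 16, seed = 0) {
  stopifnot(inherits(space, "mol_space"), !is.null(space$fp),
            noise >= 0, noise <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nmol <- space$nmol
  solv_fp <- matrix(as.integer(runif(n_solvents * nbits_solvent) < 0.5),
                    nrow = n_solvents)
  p <- ncol(space$fp) + nbits_solvent
  if (is.null(rule)) {
    rule <- numeric(p)
    nz <- sample(p, max(1L, round(0.1 * p)))
    rule[nz] <- rnorm(length(nz))
  }
  stopifnot(length(rule) == p)
  if (all(rule == 0)) stop("degenerate rule: all weights zero")
  grid <- expand.grid(mol = seq_len(nmol), solv = seq_len(n_solvents))
  X <- cbind(space$fp[grid$mol, , drop = FALSE],
             solv_fp[grid$solv, , drop = FALSE])
  colnames(X) <- c(sprintf("mol_bit%04d", seq_len(ncol(space$fp))),
                   sprintf("solv_bit%04d", seq_len(nbits_solvent)))
  z <- as.numeric(X %*% rule)
  s <- if (sd(z) > 0) stats::plogis((z - mean(z)) / sd(z)) else
    rep(0.5, length(z))
  category <- as.integer(cut(s, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                             labels = FALSE)) - 1L
  label_true <- category %in% c(3L, 4L)
  flip <- runif(length(label_true)) < noise
  label <- xor(label_true, flip)
  tab <- data.frame(
    molecule_id = space$ids[grid$mol],
    solvent_id = sprintf("SY%02d", grid$solv),
    peak_found = category > 0L,
    fwhm_r = s, area_r = s,
    category = category, label_good = label,
    stringsAsFactors = FALSE
  )
  list(table = tab, features = X,
       truth = list(rule = rule, score = z, label_true = label_true))
}
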