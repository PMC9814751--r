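# ---------------------------------------------------------------------------
# Good-solvent classification and indicator regression: pair features,
# repeated-split random-forest protocol, shadow-feature importance
# ---------------------------------------------------------------------------

# element counts from a Hill formula string like "C7H6O2"
.formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Open 2-D descriptors for one molecule
#'
#' A fixed-length physicochemical descriptor vector computed with OpenBabel:
#' molecular weight, average atomic weight (MW per atom, H included), logP,
#' molar refractivity, TPSA, H-bond acceptor/donor counts, fluorine count,
#' element counts (C, H, N, O, halogens), heavy-atom count and hydrogen
#' percentage. These are open analogues of the common commercial constitution/
#' lipophilicity descriptors (AMW, MW, Mv, H%, nH, MLOGP/ALOGP, P_VSA-like).
#'
#' @param smiles a single valid SMILES.
#' @return named numeric vector (fixed order).
#' @export
open_descriptors <- function(smiles) {
  p <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity))
  cnt <- .formula_counts(p$formula[1])
  g <- function(e) as.numeric(if (e %in% names(cnt)) cnt[[e]] else 0)
  n_atoms <- sum(cnt)
  n_heavy <- n_atoms - g("H")
  c(MW = as.numeric(p$MW[1]),
    AMW = as.numeric(p$MW[1]) / n_atoms,
    logP = as.numeric(p$logP[1]),
    MR = as.numeric(p$MR[1]),
    TPSA = as.numeric(p$TPSA[1]),
    HBA = as.numeric(p$HBA2[1]),
    HBD = as.numeric(p$HBD[1]),
    nF = g("F"),
    nC = g("C"), nH = g("H"), nN = g("N"), nO = g("O"),
    nHal = g("F") + g("Cl") + g("Br") + g("I"),
    nHeavy = n_heavy,
    Hpct = 100 * g("H") / n_atoms)
}

#' Feature vector for a molecule-solvent pair
#'
#' Concatenates a molecule block and a solvent block. In `ecfp` mode both
#' blocks are ECFP6 bit vectors; in `descriptors` mode both are
#' [open_descriptors()] vectors. The solvent block always follows the
#' molecule block.
#'
#' @param mol_smiles,solvent_smiles single SMILES strings.
#' @param mode `"ecfp"` or `"descriptors"`.
#' @param nbits fingerprint length per block in ecfp mode (default 1024).
#' @return named numeric vector; names are prefixed `mol_` / `solv_`.
#' @export
pair_features <- function(mol_smiles, solvent_smiles,
                          mode = c("ecfp", "descriptors"), nbits = 1024) {
  mode <- match.arg(mode)
  if (mode == "ecfp") {
    mb <- as.numeric(ecfp6(mol_smiles, nbits = nbits)[1, ])
    sb <- as.numeric(ecfp6(solvent_smiles, nbits = nbits)[1, ])
    names(mb) <- sprintf("mol_bit%04d", seq_along(mb))
    names(sb) <- sprintf("solv_bit%04d", seq_along(sb))
  } else {
    mb <- open_descriptors(mol_smiles)
    sb <- open_descriptors(solvent_smiles)
    names(mb) <- paste0("mol_", names(mb))
    names(sb) <- paste0("solv_", names(sb))
  }
  c(mb, sb)
}

#' Feature matrix for an evaluation table
#'
#' Builds one [pair_features()] row per evaluation, dropping constant-valued
#' columns. Solvents whose feature blocks collide (identical vectors, as can
#' happen for coarse fingerprint bits) are detected and reported in the
#' `"collisions"` attribute and a message.
#'
#' @param evals data.frame with `molecule_id`, `solvent_id`.
#' @param molecules data.frame mapping `id` to `smiles` for molecules.
#' @param solvents data.frame mapping `id` to `smiles` for solvents
#'   (default [solvent_table()]).
#' @param mode,nbits passed to [pair_features()].
#' @return numeric matrix, rows aligned with `evals`.
#' @export
pair_feature_matrix <- function(evals, molecules, solvents = solvent_table(),
                                mode = c("ecfp", "descriptors"),
                                nbits = 1024) {
  mode <- match.arg(mode)
  # compute blocks once per unique structure
  featfun <- if (mode == "ecfp") {
    function(s) as.numeric(ecfp6(s, nbits = nbits)[1, ])
  } else {
    function(s) unname(open_descriptors(s))
  }
  mblocks <- lapply(setNames(molecules$smiles, molecules$id), featfun)
  sblocks <- lapply(setNames(solvents$smiles, solvents$id), featfun)
  dup <- list()
  sids <- names(sblocks)
  for (i in seq_along(sblocks)) for (j in seq_len(i - 1L)) {
    if (identical(sblocks[[i]], sblocks[[j]])) {
      dup[[length(dup) + 1L]] <- c(sids[j], sids[i])
    }
  }
  if (length(dup)) {
    message("solvent feature collision(s): ",
            paste(vapply(dup, paste, character(1), collapse = "="),
                  collapse = ", "))
  }
  X <- t(vapply(seq_len(nrow(evals)), function(r) {
    c(mblocks[[as.character(evals$molecule_id[r])]],
      sblocks[[as.character(evals$solvent_id[r])]])
  }, numeric(length(mblocks[[1]]) + length(sblocks[[1]]))))
  nm <- if (mode == "ecfp") {
    c(sprintf("mol_bit%04d", seq_len(nbits)),
      sprintf("solv_bit%04d", seq_len(nbits)))
  } else {
    c(paste0("mol_", names(open_descriptors("O"))),
      paste0("solv_", names(open_descriptors("O"))))
  }
  colnames(X) <- nm
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  X <- X[, keep, drop = FALSE]
  attr(X, "collisions") <- dup
  X
}

#' Protocol settings for the repeated-split random-forest evaluation
#'
#' Defaults follow the study protocol: 100 random 80/20 splits, per-split
#' grid search by 5-fold cross-validation over `n_estimators` in
#' \{100, 300, 500\} and `max_depth` in \{2, ..., 10\}.
#'
#' @param n_iterations number of repeated splits.
#' @param test_fraction held-out fraction per split.
#' @param cv_folds folds for the grid search.
#' @param n_estimators_grid,max_depth_grid hyperparameter grids.
#' @param seed base RNG seed; iteration i uses `seed + i`.
#' @param grid_per_iteration run the grid search inside every iteration
#'   (default TRUE) or once on the first split and reuse the winner.
#' @return list of class `ml_protocol`.
#' @export
ml_protocol <- function(n_iterations = 100, test_fraction = 0.2,
                        cv_folds = 5, n_estimators_grid = c(100, 300, 500),
                        max_depth_grid = 2:10, seed = 0,
                        grid_per_iteration = TRUE) {
  stopifnot(n_iterations >= 1, test_fraction > 0, test_fraction < 1,
            cv_folds >= 2, length(n_estimators_grid) >= 1,
            length(max_depth_grid) >= 1)
  structure(list(n_iterations = n_iterations, test_fraction = test_fraction,
                 cv_folds = cv_folds, n_estimators_grid = n_estimators_grid,
                 max_depth_grid = max_depth_grid, seed = seed,
                 grid_per_iteration = grid_per_iteration),
            class = "ml_protocol")
}

.rf_fit <- function(x, y, task, num.trees, max.depth, seed) {
  df <- data.frame(y = y, x, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = "y", data = df,
    num.trees = num.trees, max.depth = max.depth,
    classification = (task == "classify"),
    probability = FALSE, seed = seed, num.threads = 1,
    respect.unordered.factors = TRUE
  )
}

.rf_predict <- function(fit, x) {
  stats::predict(fit, data = data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions
}

.class_metrics <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(accuracy = mean(truth == pred), precision = precision,
    recall = recall, f1 = f1)
}

.regr_metrics <- function(truth, pred) {
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  c(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    mae = mean(abs(truth - pred)))
}

.grid_search <- function(x, y, task, protocol, seed) {
  grid <- expand.grid(num.trees = protocol$n_estimators_grid,
                      max.depth = protocol$max_depth_grid)
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(protocol$cv_folds), n))
  score <- vapply(seq_len(nrow(grid)), function(g) {
    s <- vapply(seq_len(protocol$cv_folds), function(k) {
      tr <- fold != k
      if (task == "classify" && length(unique(y[tr])) < 2) return(NA_real_)
      fit <- .rf_fit(x[tr, , drop = FALSE], y[tr], task,
                     grid$num.trees[g], grid$max.depth[g], seed + 1000 * k)
      pred <- .rf_predict(fit, x[!tr, , drop = FALSE])
      if (task == "classify") mean(pred == y[!tr])
      else -mean(abs(pred - y[!tr]))
    }, numeric(1))
    mean(s, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(score), ]
}

#' Repeated-split random-forest protocol
#'
#' For each iteration: a fresh random 80/20 train/test split, hyperparameter
#' grid search by k-fold cross-validation on the training side (scored by
#' accuracy for classification, negative MAE for regression), a refit with
#' the winning setting, and train/test metrics. Splits whose training side is
#' single-class are resampled (with a message). Fully reproducible from the
#' protocol seed.
#'
#' @param x numeric feature matrix.
#' @param y response: logical/two-level for `task = "classify"`, numeric for
#'   `task = "regress"`.
#' @param task `"classify"` or `"regress"`.
#' @param protocol an [ml_protocol()].
#' @return object of class `model_report`: per-iteration metric data.frame
#'   (`metrics`), summary table (`summary`: mean, sd, quartiles), and the
#'   per-iteration winning hyperparameters (`best_params`).
#' @export
run_protocol <- function(x, y, task = c("classify", "regress"),
                         protocol = ml_protocol()) {
  task <- match.arg(task)
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= 25)
  if (task == "classify") {
    y <- as.logical(y)
    if (length(unique(y)) < 2) stop("single-class labels")
  } else {
    y <- as.numeric(y)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  n <- nrow(x)
  n_test <- max(1L, round(protocol$test_fraction * n))
  rows <- list()
  params <- list()
  best_fixed <- NULL
  for (it in seq_len(protocol$n_iterations)) {
    it_seed <- protocol$seed + it
    set.seed(it_seed)
    for (try in 1:100) {
      test_idx <- sample(n, n_test)
      ytr <- y[-test_idx]
      if (task != "classify" || length(unique(ytr)) >= 2) break
      message("iteration ", it, ": single-class training split; resampled")
    }
    xtr <- x[-test_idx, , drop = FALSE]
    xte <- x[test_idx, , drop = FALSE]
    yte <- y[test_idx]
    best <- if (protocol$grid_per_iteration || is.null(best_fixed)) {
      .grid_search(xtr, ytr, task, protocol, it_seed)
    } else best_fixed
    if (is.null(best_fixed)) best_fixed <- best
    fit <- .rf_fit(xtr, ytr, task, best$num.trees, best$max.depth, it_seed)
    mfun <- if (task == "classify") .class_metrics else .regr_metrics
    m_tr <- mfun(ytr, .rf_predict(fit, xtr))
    m_te <- mfun(yte, .rf_predict(fit, xte))
    rows[[it]] <- c(iteration = it,
                    setNames(m_tr, paste0(names(m_tr), "_train")),
                    setNames(m_te, paste0(names(m_te), "_test")))
    params[[it]] <- data.frame(iteration = it, n_estimators = best$num.trees,
                               max_depth = best$max.depth)
  }
  metrics <- as.data.frame(do.call(rbind, rows))
  summ <- do.call(rbind, lapply(setdiff(names(metrics), "iteration"),
    function(col) {
      v <- metrics[[col]]
      data.frame(metric = col, mean = mean(v), sd = sd(v),
                 q25 = as.numeric(quantile(v, 0.25)),
                 q50 = as.numeric(quantile(v, 0.50)),
                 q75 = as.numeric(quantile(v, 0.75)))
    }))
  structure(list(task = task, metrics = metrics, summary = summ,
                 best_params = do.call(rbind, params), protocol = protocol),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> task:", x$task, "|",
      x$protocol$n_iterations, "iterations\n")
  s <- x$summary
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %.3f (SD %.3f)\n", s$metric[r], s$mean[r], s$sd[r]))
  }
  invisible(x)
}

#' Shadow-feature importance screening
#'
#' Boruta-style relevance test: in each run, every feature is paired with a
#' row-permuted shadow copy, a random forest is fitted on the joined matrix,
#' and a feature scores a hit when its impurity importance exceeds the
#' maximum shadow importance. After `max_runs` runs, features with
#' significantly more (fewer) hits than the 50% binomial null are confirmed
#' (rejected); the rest stay tentative.
#'
#' @param x numeric feature matrix.
#' @param y response (as in [run_protocol()]).
#' @param task `"classify"` or `"regress"`.
#' @param max_runs number of shadow runs (default 30).
#' @param n_trees trees per forest (default 300).
#' @param p_cut two one-sided binomial significance cutoffs (default 0.01).
#' @param seed RNG seed.
#' @return data.frame (`feature`, `hits`, `runs`, `decision`) sorted by hits,
#'   decision in `confirmed`/`tentative`/`rejected`.
#' @export
important_features <- function(x, y, task = c("classify", "regress"),
                               max_runs = 30, n_trees = 300, p_cut = 0.01,
                               seed = 0) {
  task <- match.arg(task)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (task == "classify") y <- as.logical(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  p <- ncol(x)
  hits <- integer(p)
  for (run in seq_len(max_runs)) {
    set.seed(seed + run)
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(x))
    df <- data.frame(y = y, cbind(x, shadow), check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "y", data = df, num.trees = n_trees,
      importance = "impurity", classification = (task == "classify"),
      seed = seed + run, num.threads = 1
    )
    imp <- ranger::importance(fit)
    thr <- max(imp[(p + 1):(2 * p)])
    hits <- hits + as.integer(imp[1:p] > thr)
  }
  p_hi <- stats::pbinom(hits - 1, max_runs, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, max_runs, 0.5)
  decision <- ifelse(p_hi < p_cut, "confirmed",
                     ifelse(p_lo < p_cut, "rejected", "tentative"))
  out <- data.frame(feature = colnames(x), hits = hits, runs = max_runs,
                    decision = decision, stringsAsFactors = FALSE)
  out[order(-out$hits), ]
}
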