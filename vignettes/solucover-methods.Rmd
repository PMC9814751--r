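---
title: "Coverage-driven molecule prioritization and UV-Vis solubility indicators: methods"
author: "solucover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-driven molecule prioritization and UV-Vis solubility indicators: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solucover)
```

# The problem

Freshly synthesized tetraphenylporphyrin (TPP) dyes are often insoluble or
aggregate in common solvents, which distorts every optical measurement made on
them. Early-stage exploration of a TPP-derivative family therefore needs three
things at once: a *practical* chemical space (what could actually be made in
one step from accessible materials), a *rational evaluation order* over that
space (synthesis is expensive; each evaluated molecule should teach us about as
many unevaluated ones as possible), and a *reduction of messy UV-Vis spectra*
to a few indicators that can carry solubility labels into machine-learning
models. solucover implements that loop: enumeration, prioritization,
spectrum reduction, and model estimation, plus synthetic-data generators that
make every stage testable against known ground truth.

# Chemical-space enumeration

`enumerate_products()` applies three one-step couplings between cores and
small substituents (`filter_substituents()` enforces the MW < 200 g/mol
cutoff, strict inequality):

* **amide**: core carboxylic acid + primary/secondary amine (water leaves),
* **ester**: core carboxylic acid + alcohol/phenol,
* **ether**: Williamson coupling, in both orientations — core hydroxyl +
  substituent alkyl halide, and core halide + substituent hydroxyl.

Since no SMIRKS-transform engine is available in this stack, the templates are
implemented as explicit graph edits: functional groups are perceived on the
parsed heavy-atom graph (carbonyl, hydroxyl, amine, halide, ring membership),
the leaving group is deleted, the new bond is formed, and the product is
re-canonicalized by OpenBabel, which also performs valence sanitization —
products that fail it are dropped and logged, never raised. Products are
deduplicated by canonical SMILES, and each one carries its
(core, substituent, reaction) provenance.

Two deliberate choices:

* **`site_mode = "all_sites"` is the default**: symmetric tetra-arm TPP cores
  are modified at every arm simultaneously, matching one-step full-conversion
  syntheses of symmetric derivatives. `single_site` is retained for
  generality; its mono-substituted porphyrin products can appear twice because
  the kekulized connection table distinguishes the two central NH tautomer
  positions — chemically these are the same compound, and the all-arms default
  avoids the issue entirely.
* **Amine perception excludes all ring nitrogens.** The kekulized table cannot
  separate pyrrole-type NH (the unreactive porphyrin core nitrogens, which
  must never be acylated) from genuinely reactive aliphatic ring amines such
  as piperidine. Excluding both costs a little recall on exotic substituents
  and protects every porphyrin core; it is the conservative side of the
  trade-off.

Free acids (not acid chlorides) are assumed on the acid side, and the halide
is the leaving group on the ether side.

# Fingerprints, neighbors, coverage

Similarity is Tanimoto distance over ECFP6 (radius-3 circular) fingerprints,
computed by OpenBabel in its native 4096-bit form and folded by bitwise OR to
`nbits` (default 2048). Hash collisions make individual bit identities
backend-specific, so all tests compare distances and coverages, never bits.

A `mol_space` stores the pairwise distance matrix (dense; the intended scale
is up to ~10^4 molecules) and the neighbor relation
$C_S(m_i) = \{ m_j \in S : d_{ij} < D_{TH} \}$ with **strict** inequality and
default $D_{TH} = 0.3$. Every molecule is its own neighbor whenever
$D_{TH} > 0$ (d_ii = 0), which matters at small budgets: one isolated pick
still covers itself. With unit weights (the default) the coverage of a
selection is simply the fraction of molecules within the threshold of any
selected molecule; `order = 2` expands once more through the neighbor relation
("neighbors of neighbors") and is the default benchmark curve, with order 1
emitted alongside. The cover function has diminishing marginal returns
(submodularity), which is what makes greedy selection near-optimal and is
verified exhaustively in the tests.

# Greedy prioritization with an evaluated-neighborhood penalty

At step $i$ the greedy selector maximizes

$$ f^i(m) \;=\; \mathrm{Count}\{\, j \ \text{uncovered} : d_{mj} < D_{TH} \,\}
\;-\; \lambda \, N \,\mathrm{Count}\{\, j \ \text{evaluated} : d_{mj} < D_{TH} \,\} $$

where $N$ is the space size. The first term is the marginal coverage gain; the
second penalizes candidates that sit inside already-evaluated neighborhoods.
With $\lambda = 1$ (the default, maximal penalty) the penalty magnitude
$N$ dominates any possible gain ($< N$), so a candidate adjacent to an
evaluated molecule can never outrank one that is free of evaluated neighbors
and still gains something — duplicated evaluations are suppressed as hard as
possible. Weights and penalties are injectable for generality; the defaults
(unit weights, unit penalty on evaluated molecules) reduce the general
weighted form to the counting form above.

Ties in the argmax are broken deterministically by canonical-SMILES
lexicographic order (index order for synthetic spaces without SMILES), so
rankings are exactly reproducible.

Two baselines are provided. `rank_random()` is a seeded uniform permutation.
`rank_unc()` is Gaussian-process uncertainty sampling ("least confident"
selection): the kernel is Tanimoto similarity ($K = 1 - d$) with unit prior
variance and no hyperparameter optimization, the first pick is the molecule
with the largest summed distance to all others, and each later step picks the
candidate with maximal posterior variance. Posterior variance depends only on
the evaluated inputs — no response values enter anywhere, which is the
defining property of uncertainty sampling with a fixed kernel. Because
similarity matrices derived from arbitrary user-supplied distance matrices
need not be positive semi-definite, the evaluated block falls back to
eigenvalue clipping when plain Cholesky fails; genuine fingerprint Tanimoto
kernels never need it.

# Spectrum reduction

Each baseline-subtracted spectrum is reduced inside the Soret search window
(default 380–470 nm; the weaker Q band near 520 nm is excluded) to four
indicators:

* $\lambda_{max}$, Intensity and FWHM from a **single-Gaussian** least-squares
  fit (`minpack.lm`),
* Area from a **two-Gaussian** fit (main component plus a shoulder constrained
  to the shorter-wavelength side, initialized 15 nm blue-shifted at 30%
  height), as the *analytic* area of the main component
  $h \cdot w \cdot \sqrt{\pi / (4 \ln 2)}$ — not a numeric integral of the raw
  curve, so aggregate shoulders do not inflate it.

Two numerical guards matter in practice:

* **No-peak criterion** (the data's failure labels): a spectrum is peakless if
  the fit does not converge, or the fitted height is below an absolute floor
  (default 0.005 absorbance) or below 5x the RMS fit residual. Thresholds are
  configurable.
* **Shoulder acceptance** (`shoulder_gain`, default 0.7): the two-Gaussian
  decomposition is used for the area only when its RMS residual is below 0.7x
  the single-Gaussian RMS. A genuine shoulder produces a large single-fit
  misfit and a near-noise-floor two-fit, passing easily; a plain Gaussian plus
  noise gives no real improvement, and without this rule the second component
  drifts under the main peak and silently steals up to half its area.

Fitting is performed on the wavelength axis (the axis the spectra are recorded
on); `nm_to_ev()` and `fwhm_nm_to_ev()` convert for energy-axis comparisons,
where typical sharp Soret widths are ~0.1 eV.

Per molecule, the relative indicators are
$FWHM_r = FWHM_{min}/FWHM$ and $Area_r = Area/Area_{max}$, extrema taken over
the solvents where a peak was found. Both live in [0, 1], equal 1 in the
molecule's most suitable solvent, are invariant to rescaling all of a
molecule's absorbances, and are (0, 0) for no-peak pairs. `categorize()` runs
K-means (default $K = 5$, 25 restarts, seeded) on the (FWHM_r, Area_r) points
and maps clusters to ordinal categories 0–4 by ascending centroid sum, so 0 is
the origin cluster (insoluble/aggregated) and 4 the sharp-and-large corner.
No-peak pairs are forced to category 0 a priori by default (they are exact
(0,0) points and would otherwise pin a cluster); `include_nopeak = TRUE`
clusters them instead. The centroid-sum ordering is an implementation rule
standing in for a manual, axis-based category assignment; "good solvent"
means category 3 or 4 (configurable).

# Model estimation

`pair_features()` concatenates a molecule block and a solvent block — ECFP6
bits in `ecfp` mode, or an open physicochemical descriptor set (`descriptors`
mode: MW, AMW, logP, molar refractivity, TPSA, H-bond counts, element counts,
H%) computed with OpenBabel as an open stand-in for commercial
constitutional/lipophilicity descriptors. Constant columns are dropped, and
solvents whose blocks collide (coarse fingerprints cannot always separate
small solvents) are detected and reported rather than silently merged.

`run_protocol()` repeats, per iteration: a fresh random 80/20 split,
hyperparameter grid search by 5-fold cross-validation on the training side
(random forests via `ranger`; grids default to 100/300/500 trees and depth
2–10; scored by accuracy for classification, negative MAE for regression),
a refit with the winning setting, and train/test metrics (accuracy, precision,
recall, F1 with "good solvent" as the positive class; R^2 and MAE for
regression). Per-iteration seeds derive deterministically from the base seed,
single-class training splits are resampled with a message, and summaries
report mean, SD and quartiles over the iteration distribution. The grid search
runs inside every iteration by default (`grid_per_iteration = FALSE` reuses
the first winner when runtime matters).

`important_features()` is a shadow-feature relevance screen: each run appends
a row-permuted copy of every feature, fits a forest with impurity importance,
and scores a hit for features beating the best shadow; after a fixed number of
runs, hits are tested against the 50% binomial null (confirm / reject /
tentative). This is a single-pass variant of the iterative shadow-feature
algorithm — features are not dropped between runs — which is simpler, fully
deterministic per seed, and adequate at these feature counts.

# Synthetic data: what it emulates, what it does not

The generators exist so that every stage has an oracle without any downloads:

* `synth_space()` plants clusters in fingerprint space: random prototype bit
  sets (density 0.5) with independent per-bit flips (default 5%). With these
  defaults within-cluster Tanimoto distances concentrate near ~0.17 and
  between-cluster distances near ~0.67, so the default threshold 0.3 cleanly
  separates planted structure — mimicking the clustered topology of a real
  derivative space while staying chemistry-free (selector tests decouple from
  parsing). It does not emulate the *size imbalance* or continuous density
  gradients of a real enumerated space.
* `synth_spectrum()` sums Gaussian components plus iid noise and returns the
  main component's analytic indicators. Real aggregate shoulders are neither
  perfectly Gaussian nor independent of the main peak; passing fit-recovery
  tests here demonstrates correct deconvolution of the assumed model, not
  spectral physics.
* `synth_solubility_table()` plants a linear structure-solubility rule: a
  weight vector over pair features scored, squashed to [0, 1], thresholded
  into categories at 0.2/0.4/0.6/0.8, with optional label flips. Noiseless
  tables are perfectly learnable; 50% flips give the null model.

Consequently, green tests on synthetic data certify the machinery
(enumeration, selection, fitting, protocol bookkeeping) — they do not certify
prediction accuracy on real TPP measurements, which requires the deposited
experimental dataset.

# Problem sizes and runtime choices

Test and benchmark sizes are chosen to exercise the mathematics at desk
scale: greedy-vs-exhaustive equivalence on 100 random spaces up to 64
molecules, submodularity on 10^4 random set triples, selector benchmarking on
500-molecule/20-cluster spaces with 100 random-baseline seeds, fit recovery on
200 random spectra at SNR 50, and the full 100-iteration split protocol on a
240-row planted table with a reduced grid (100 trees, depth {4, 8}) — the
full 27-point grid is the default for real analyses. The dense distance
matrix is the intended representation up to ~10^4 molecules; beyond that a
blocked computation would be needed.

# Known limitations

* Porphyrin NH tautomers are distinct kekulized structures; deduplication is
  by canonical SMILES, so single-site products of symmetric cores can appear
  as two tautomer-related entries.
* Ring amines are never treated as substituent handles (see above).
* Multi-fragment (salt-form) SMILES are not desalted; supply parent
  structures.
* The published headline coverages (36/40/63% at 5/10/100 evaluations, ~13%
  random mean at 10, 24.8% for the 15 evaluated molecules) and the 240/215/25
  spectrum counts belong to the deposited ~6k-molecule experimental dataset;
  the corresponding checks run only when that dataset is placed under
  `inst/extdata/deposited/`. Reported coverage summaries can also differ
  depending on whether order-1 or order-2 curves are quoted — both are always
  computed and written side by side rather than reconciled.
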