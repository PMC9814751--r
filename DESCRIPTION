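Package: solucover
Title: Coverage-Driven Molecule Prioritization and UV-Vis Solubility Indicators
    for Porphyrin Dyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for an early-stage, semi-automated exploration of
    tetraphenylporphyrin-like dye chemistry. Enumerates a practical chemical
    space by applying one-step reaction templates (amide formation,
    esterification, Williamson ether synthesis) to accessible cores and small
    substituents; prioritizes molecules for experimental evaluation by greedy
    submodular cover maximization over an ECFP6/Tanimoto neighbor graph, with
    random- and Gaussian-process-uncertainty-sampling baselines and coverage
    benchmarking; reduces UV-Vis absorption spectra to four solubility
    indicators (peak position, intensity, FWHM, area) by Gaussian deconvolution
    and categorizes molecule-solvent pairs by K-means on relative indicators;
    and fits random-forest classification and regression models of solubility
    under a repeated-split protocol with cross-validated grid search and
    shadow-feature importance analysis. Includes synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    minpack.lm,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
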