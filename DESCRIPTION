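Package: plsmem
Title: Partial Least Squares Analysis of Recognition-Memory fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and multivariate analysis of event-related
    recognition-memory fMRI experiments with a payoff (retrieval-goal)
    manipulation. Provides a synthetic experiment generator (word pool,
    counterbalanced study/test design, signal-detection response model),
    behavioral statistics (hit and correct-rejection rates, d-prime and
    criterion, paired t with Cohen's dz, TOST equivalence tests, two-way
    repeated-measures ANOVA), a condition-level image simulator with planted
    latent task patterns and seed-coupled voxels, a canonical-HRF GLM for
    beta estimation, mean-centered task PLS and seed (functional
    connectivity) PLS via singular value decomposition, permutation tests
    of latent variables, bootstrap salience reliability (bootstrap ratios),
    and peak-table reporting on voxel grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
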