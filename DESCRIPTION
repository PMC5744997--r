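Package: tastemap
Title: Best-Stimulus Prevalence Mapping of Gustatory fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related gustatory
    fMRI on a cortical surface patch. Generates synthetic multi-subject BOLD
    recordings under a tastant delivery protocol with a planted chemotopic
    layout, fits mass-univariate general linear models with canonical
    hemodynamic response regressors, applies motion-based subject exclusion,
    aligns subjects by curvature-driven monotone warps toward a moving
    average template, computes random-effects group statistics with
    cluster-level family-wise-error control by sign-flip permutation, and
    builds best-stimulus ("prevalence") maps: per-vertex z-scored taste
    ranking, winner maps with saturation coding, normalized preference
    scores, taste-exclusion remapping, and individual-to-group map
    similarity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
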