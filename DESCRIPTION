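Package: avbci
Title: Bayesian Causal Inference Modelling and Neural Decoding for
    Audiovisual Spatial Localisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers localise synchronous auditory
    and visual signals under spatial conflict (the ventriloquist paradigm).
    Implements the hierarchical Bayesian causal inference observer model with
    model-averaging, model-selection and probability-matching decision rules,
    maximum-likelihood fitting of discrete localisation responses by Monte
    Carlo marginalisation with grid search plus simplex refinement, scaled
    coefficients of determination, and BIC-based random-effects Bayesian model
    selection with protected exceedance probabilities. Provides the circular
    audiovisual weight index (four-quadrant angle of visual and auditory
    regression weights) with von Mises likelihood-ratio permutation tests and
    cluster correction, linear support-vector-regression decoding of spatial
    estimates from trials-by-channels-by-time activity with temporal
    generalisation within and across modalities, and synthetic-data
    generators for the full 4x4x2x2 factorial design so every stage runs
    end-to-end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
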