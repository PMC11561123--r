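Package: stimmap
Title: Sweet-Spot Mapping and Fiber Filtering for Deep Brain Stimulation Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise stimulation sweet-spot maps and streamline
    connectivity (fiber-filtering) models from deep brain stimulation
    cohorts, scores independent patients against both models by spatial
    rank correlation, and validates the scores against clinical motor
    outcomes. Includes a simplified point-source electric-field model, a
    synthetic two-cohort generator with planted ground truth, clinical
    outcome derivations (UPDRS-III change scores, levodopa equivalent
    daily dose), and permutation-based inference for small cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
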