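Package: jointcoord
Title: Joint Simon Effect and Inter-Agent Response Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dyadic go/no-go Simon experiments:
    correspondence and trial-transition coding, Tukey-fence participant
    exclusion, mean and distributional (quartile-bin) decompositions of the
    joint Simon effect, sequential (conflict-adaptation) effect tables,
    instantaneous cross-correlation of reaction-time series with a zero-phase
    exponential filter, coordination indices against pseudo-pair baselines,
    paired t-tests and within-subject ANOVAs, and mixed-model comparisons
    with response coordination as a pair-level random effect. Includes a
    synthetic dyad generator with a coupled AR(1) latent process so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
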