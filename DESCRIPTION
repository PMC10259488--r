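Package: bottlechoice
Title: Analysis of Two-Bottle Choice Nicotine Drinking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-access two-bottle choice drug-drinking
    experiments in mice, from minute-resolution per-bottle drinking logs to
    daily intake (mg/kg/day) and percent drug consumption, pseudo-ternary
    choice-index representations with apex distances and per-animal
    trajectories, avoider/non-avoider phenotype classification with
    per-animal aversion-threshold estimation, quantification of
    nicotine-evoked currents and peri-injection firing-rate changes from
    paired electrophysiology, and the nonparametric statistical toolkit
    used for group comparisons (exact Mann-Whitney and Wilcoxon signed-rank,
    tie-corrected Friedman, Holm-Bonferroni step-down, Yates-corrected
    chi-squared). Includes a bout-level synthetic cohort generator with
    behavioral archetypes for closed-loop validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
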