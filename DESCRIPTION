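Package: her2cea
Title: Markov Cohort Cost-Effectiveness Model of Adjuvant Trastuzumab in
    HER2-Positive Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-state (disease-free, local recurrence, distant
    metastases, dead) annual-cycle Markov cohort model comparing one year of
    adjuvant trastuzumab after chemotherapy with chemotherapy alone in
    HER2-positive early breast cancer, from the Dutch health-care
    perspective. Provides exponential-survival conversions between annual
    probabilities and hazard rates, hazard-ratio treatment effects with a
    bounded benefit duration, life-table background mortality,
    half-cycle-corrected discounted costs, life years and QALYs, ICER and
    dominance classification, probabilistic sensitivity analysis with
    Beta/Gamma parameter distributions, cost-effectiveness acceptability
    curves, per-patient and population expected value of perfect
    information, scenario and one-way sensitivity analyses, and a synthetic
    patient-level cohort generator with an exponential rate estimator for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
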