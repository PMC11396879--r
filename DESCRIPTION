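Package: metavulx
Title: Serum NMR Metabolic Vulnerability Indices and Covariate-Adjusted
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the composite serum vulnerability indices derived from
    proton NMR metabolite panels -- the Inflammatory Vulnerability Index (IVX,
    from GlycA and small HDL particle concentration), the Metabolic Malnutrition
    Index (MMX, from branched-chain amino acids and citrate), and the combined
    Metabolic Vulnerability Index (MVX) -- with linear anchor rescaling to a
    1-100 score. Provides a seeded synthetic-cohort generator emulating a
    three-group healthy-control / relapsing-remitting / progressive multiple
    sclerosis study design, and the full covariate-adjusted ordinary
    least-squares association machinery: group, disability (EDSS, timed
    25-foot walk), and MRI-volumetric models with Type II sums of squares,
    generalized eta-squared effect sizes, tertile stratification, and baseline
    group comparisons. All randomness flows from a single root seed so every
    run is reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    dplyr,
    withr
Config/testthat/edition: 3
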