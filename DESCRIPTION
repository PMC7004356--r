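Package: ctgtier
Title: Rule-Based 3-Tier and 5-Tier Intrapartum Fetal Heart Rate Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated cardiotocography (CTG) analysis for the last hour of
    labor. Extracts the fetal-heart-rate features that guideline rule tables
    consume (baseline, baseline variability, accelerations, deceleration type
    and severity, sinusoidal pattern), applies the NICHD 3-tier
    (Category I/II/III) and the Japanese/Parer 5-tier (Level 1-5)
    classifications to each 10-minute segment of the 60 minutes before
    delivery, and relates segment classifications to umbilical artery pH and
    base excess at delivery with nonparametric tests (Friedman,
    Kruskal-Wallis, Wilcoxon, Tukey HSD). Includes a synthetic CTG cohort
    generator so every pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
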