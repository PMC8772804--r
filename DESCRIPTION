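Package: EnteroShift
Title: Enterotype Dynamics and Dysbiosis Screening in Weight-Loss Microbiome Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse shotgun gut-metagenome cohorts followed through a
    weight-loss intervention: consolidation of per-read taxonomic assignments
    into rarefied abundance tables with a two-step false-positive filter,
    alpha/beta diversity and ordination statistics (PCoA, distance-based
    redundancy analysis, PERMANOVA), Dirichlet multinomial mixture (DMM)
    enterotyping with model-order selection and semantic labelling of the
    dysbiotic Bacteroides 2 (Bact2) state, adjusted cross-sectional association
    models, paired-visit longitudinal analyses (enterotype transitions,
    fold-change stratification, linear mixed models), pan-genome KO and gut
    metabolic module aggregation, and propensity-score matching of supplement
    arms. A synthetic-cohort generator with a recorded truth channel makes the
    whole pipeline testable without access to the original cohort.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
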