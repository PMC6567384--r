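Package: poachCMR
Title: Multievent Capture-Mark-Recapture Estimation of Poaching Mortality
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates cause-specific (poaching versus other) mortality from
    annual encounter histories of individually marked animals carrying mixed
    mark types (ear tags, optical collars, GPS collars). Implements a
    9-state/11-event multievent hidden-Markov likelihood that jointly models
    tag loss (GPS signal failure and collar drop-off), mark-dependent
    resighting, incomplete dead recovery and uncertainty over the cause of
    death, with maximum-likelihood fitting, AICc model selection, Akaike-weight
    model averaging, Cormack-Jolly-Seber goodness-of-fit components and a
    generative simulator of the full marking-mortality-observation process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
biocViews: Survival, HiddenMarkovModel, Epidemiology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'age-partition.R'
    'encounter-data.R'
    'estimation.R'
    'gof.R'
    'model-structure.R'
    'multievent-core.R'
    'pipeline.R'
    'poachCMR-package.R'
    'selection.R'
    'synthetic-data.R'
    'utils-links.R'
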