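Package: ddPCRclock
Title: Multiplex ddPCR Methylation Quantification and Six-CpG Epigenetic Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Droplet-level DNA methylation quantification for an amplitude-based
    multiplex droplet digital PCR (ddPCR) assay targeting six age-associated CpG
    sites (ASPA, C1orf132, CCDC102B, EDARADD, ELOVL2, FHL2), with Poisson
    limiting-dilution statistics (occupancy, absolute copy estimates,
    single-molecule fraction) and quality-control gates. Includes seeded
    simulators for droplet wells (Poisson partitioning, amplitude clusters,
    'rain' artifacts, dilution series) and for age-structured methylation
    cohorts, plus training and evaluation of six-CpG age-prediction models:
    elastic net, gradient boosting, linear and radial support vector
    regression, and a Klemera-Doubal biological-age estimator, with
    nonlinearity-correcting preprocessing, age-acceleration utilities and
    exhaustive CpG-subset search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, glmnet, xgboost, e1071, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'kdr.R'
    'preprocess.R'
    'clocks.R'
    'droplets.R'
    'io.R'
    'poisson.R'
    'simulate-cohort.R'
    'simulate-droplets.R'
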