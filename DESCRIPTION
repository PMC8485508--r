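Package: mbrecov
Title: Longitudinal Microbiome Perturbation-Recovery Analysis with
    Bayesian Gaussian-Process Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal gut-microbiome responses to
    antibiotic perturbation and fecal transfaunation: feature-table
    filtering, rarefaction and taxonomic collapsing; centered log-ratio
    transforms with Dirichlet Monte-Carlo resampling of sequencing-count
    uncertainty; Shannon alpha diversity, unweighted UniFrac beta
    diversity, distance-from-baseline recovery series and principal
    coordinates ordination; penalized group-smooth trajectory models with
    animal-level permutation contrasts; a Bayesian multivariate
    Gaussian-process covariation engine (matrix-normal/inverse-Wishart)
    that extracts significant and strong taxon-taxon association
    networks from irregularly sampled compositional count series; and
    antibiotic-resistance-gene (resistome) summaries. Includes a
    ground-truthed synthetic-data generator emulating a three-group
    (control, antibiotic, antibiotic plus transfaunation) longitudinal
    study design, so every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    rlang,
    splines,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    mgcv,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
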