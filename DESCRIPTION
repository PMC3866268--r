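Package: radshift
Title: Diversification Rates and Climate-Niche Evolution in Species Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-phylogenetics pipeline for studying climate-driven
    radiations. Estimates clade net diversification rates under the
    Magallon-Sanderson estimator with extinction fractions, the gamma
    statistic with a Monte Carlo constant-rates (MCCR) correction for
    incomplete sampling, and likelihood-based selection among rate-constant
    (pure birth, birth-death) and rate-variable (density-dependent,
    multi-rate Yule) diversification models. Quantifies rates of climate
    niche evolution in felsens from phylogenetically independent contrasts,
    partitions trait variation into phylogenetic (Pagel's lambda), spatial
    and independent components by joint maximum likelihood, and measures
    climate-niche overlap between species with background-corrected kernel
    occupancy profiles, Schoener's D and a permutation niche-equivalency
    test. Includes a synthetic-data generator (birth-death trees, traits
    with tunable phylogenetic and spatial signal, gradient landscapes,
    climate-suitability occurrence sampling) so every stage is testable
    without external data, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    geosphere,
    MASS,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
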