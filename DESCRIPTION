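Package: treelim
Title: Bayesian Limitation Modelling of Pantropical Tree Cover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A limitation-factor framework for fractional tropical tree
    cover. Tree cover is modelled as a maximum cover multiplied by logistic
    limitations from five controls (mean annual precipitation, mean annual
    temperature, shortwave radiation, a composite environmental stress index
    and a composite human-pressure index), fitted to fractional cover
    observations with a zero-inflated logit-normal likelihood by adaptive
    Metropolis-Hastings MCMC. Includes rainfall seasonality metrics, gridded
    NetCDF input/output with bilinear regridding and tropics masking, a
    posterior impact calculus (absolute and relative impacts, limitation,
    sensitivity, counterfactual fire experiments, per-unit response curves),
    area-weighted biome summaries, and a synthetic-data generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
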