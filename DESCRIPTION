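Package: pahsoilrisk
Title: Soil PAH Characterization and Multi-Route Human Health Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes polycyclic aromatic hydrocarbon (PAH)
    contamination of soils and assesses the associated human health risk.
    Provides a registry of the 16 USEPA priority PAHs with ring counts,
    molecular-weight classes and Nisbet-LaGoy toxicity equivalence factors;
    summary statistics and ring-number / molecular-weight / carcinogenic
    composition profiles for location-by-compound concentration tables;
    benzo[a]pyrene toxic-equivalent (TEQ) concentrations; incremental
    lifetime cancer risk (ILCR) via soil ingestion, inhalation and dermal
    contact for adult and child receptors; estimated daily intake and
    non-carcinogenic hazard quotients (HQ); and a seeded lognormal
    generator of synthetic site data for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
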