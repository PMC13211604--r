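Package: halorisk
Title: Halocarbon Campaign Statistics, Source Apportionment and
    Probabilistic Inhalation Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for urban volatile halogenated hydrocarbon
    (VHH) monitoring campaigns: species metadata and mixing-ratio to
    mass-concentration conversion, detection-limit filtering, composition
    and diurnal summaries, background-enhancement statistics,
    uncertainty-weighted positive matrix factorization (PMF) for source
    apportionment, deterministic and replicated Monte-Carlo inhalation
    risk assessment (lifetime cancer risk and hazard index) with MCE/SD
    convergence diagnostics, Anderson-Darling distribution selection, and
    Sobol total-order sensitivity analysis. Includes a synthetic-campaign
    generator with planted source structure for method validation.
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
    nortest,
    withr,
    yaml
Config/testthat/edition: 3
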