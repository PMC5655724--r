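Package: chainscale
Title: Scale and Chain Economies in Multiproduct Hospital Cost Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates multiproduct translog cost systems for hospital
    panel data (a cost equation plus input cost-share equations under
    symmetry and linear price homogeneity), constructs exogenous input
    price proxies, and derives the economics of interest: marginal costs,
    overall (ray) scale elasticities, product-specific scale elasticities
    with minimum-output substitution, and chain economies of sequential
    services such as an emergency-room visit followed by an inpatient
    admission.  Ships a synthetic hospital-year panel generator with a
    known ground-truth parameter set so estimation, diagnostics and the
    elasticity pipeline are fully testable without proprietary data, and
    packaged parameter fixtures for a published Dutch general-hospital
    cost system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
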