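Package: mppdyn
Title: System-Dynamics Simulation of a Patented-Drug Market under the Medicines Patent Pool
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic stock-flow simulation of a patented-drug market in which an
    originator enterprise and a government decide whether to join the Medicines Patent
    Pool (MPP). Couples exponential patent-value decay and a price/intensity drug-attraction
    index to a compartmental patient-flow model (diagnosed, in-therapy, rejected patients)
    and an economic ledger (revenues, royalties, taxes, subsidies, government medical
    expenditure). Paired in-pool/out-of-pool worlds yield join decisions; sweep harnesses
    locate the generic-price-ratio crossing, the feasible pooling-subsidy-coefficient
    interval, the royalty-rate ceiling, and R&D-scale and patent-intensity effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
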