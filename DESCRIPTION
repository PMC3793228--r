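Package: paramodiv
Title: Net Diversification Rates and Hotspot Comparison for Paramo Plant Lineages
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates net diversification rates of plant clades from standing
    diversity and crown age under pure-birth and Magallon-Sanderson
    method-of-moments estimators with a relative extinction fraction; compares
    biodiversity hotspots by mean lineage rate with percentile-bootstrap
    confidence intervals and per-area density metrics; estimates, by stratified
    Monte-Carlo resampling with an exact enumeration oracle, the probability
    that the fastest-evolving lineage belongs to each hotspot; and counts
    Pleistocene divergence events on ultrametric chronograms. Includes
    constant-rate Yule and birth-death chronogram simulators and a synthetic
    per-hotspot lineage-rate generator for validation, plus the transcribed
    Paramo lineage and hotspot tables as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
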