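Package: frostfd
Title: Summer Freezing Resistance of Alpine Plants and Its Community-Level Functional Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract ice nucleation temperature (NT) and freezing
    point (FP) from leaf cooling thermograms, estimate the lethal temperature
    LT50 from chlorophyll-fluorescence photoinactivation by bracketed linear
    interpolation, classify species freezing-resistance mechanisms (tolerant,
    avoidant, sensitive), and compute community-weighted means and Rao
    quadratic entropy on Gower trait distances over plot-by-species cover
    matrices, together with their altitudinal trend statistics
    (linear models, Kruskal-Wallis with Nemenyi post hoc, trait correlations).
    Includes a synthetic-data generator that emulates the full study design
    (cooling ramps with latent-heat exotherms, logistic freezing-damage
    curves, trait tables with rank-correlated leaf dry matter content, and
    niche-structured communities along an altitude gradient) so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
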