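Package: conduitpcp
Title: Subcellular Planar Cell Polarity from Dachsous/Fat Bridges in the
    Larval Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates planar cell polarity (PCP) of denticle-forming cells
    in the ventral abdominal epidermis of Drosophila larvae. Synthetic cell
    maps of one hemisegment (denticle rows 0-6 plus tendon rows T1 and T2)
    are given a Dachsous/Fat/Four-jointed activity landscape; Ds-Ft
    heterodimer bridges are allocated on discretised cell-cell interfaces
    and relaxed to a steady state; polarity is then read out per membrane
    subdomain through facing-membrane "conduits", so that a single cell can
    carry opposing polarities in different subdomains. Includes perturbed
    anatomies (atypical two-row cells, tendon-row gaps, ds- ft- epidermis,
    Ds-overexpressing clones), denticle placement, classification of
    denticles by abutting-neighbour type, contingency tables with a
    first-principles Fisher exact test, scenario orchestration and SVG
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
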