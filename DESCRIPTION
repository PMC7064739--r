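Package: jaggr
Title: Orientational Order and Cluster Analysis of Dye Aggregates in
    Lipid-Templated Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify J- and H-aggregation of rod-like dye
    molecules (such as indocyanine green) in periodic molecular
    configurations.  Computes the distance-resolved pairwise
    orientational order parameter O(r), close-pair angle distributions,
    the center-of-mass radial distribution function, single-linkage
    cluster statistics under a distance cutoff, and a geometric
    J-/H-aggregate classification based on the 54.7 degree magic-angle
    boundary.  Includes a synthetic configuration generator with
    controllable nematic order and planted clusters, readers for PDB,
    GRO and a tabular configuration format, and the absorbance-ratio and
    encapsulation-efficiency formulas used to characterize dye-loaded
    liposome formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
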