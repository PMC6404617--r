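Package: steriscan
Title: Structural Consequence Scanning of Protein Point Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the local structural consequences of
    amino-acid substitutions on a fixed protein template. The package
    superposes crystallographic protomer ensembles (Kabsch), measures
    side-chain chi angles, enumerates candidate rotamers from a compact
    library or a chi grid, rebuilds side chains from ideal internal
    coordinates, and scores each placement for steric clashes, van der
    Waals contacts and hydrogen bonds against its environment. Per-variant
    evidence is condensed into a consequence call (steric clash, loss of
    van der Waals contacts, loss of hydrogen bonds, or none). A companion
    module ingests cell-based inclusion-assay count tables, computes
    aggregation percentages and tests the association between predicted
    consequence and aggregation with an exact test. Synthetic fixture
    generators (mini beta-hairpins, conformer ensembles, binomial count
    tables) make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
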