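Package: pishift
Title: Isoelectric-Point Divergence Analysis for Orthologous Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes mature-protein isoelectric points (pI) from sequence
    with a Henderson-Hasselbalch charge model solved by bisection, optionally
    adjusted for phosphorylation and glycosylation; quantifies pI divergence
    between orthologous proteins of different species with a non-parametric
    shift threshold (2 x (third quartile - median) of absolute ortholog pI
    differences) and permutation significance; tests whether sites under
    positive selection are enriched among ionizable residues with an exact
    contingency test; counts minimum pI-category changes on a species tree by
    parsimony; and simulates proteome-scale ortholog pI tables, alignments
    and selection tables with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
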