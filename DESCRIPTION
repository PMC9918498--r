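Package: trypknot
Title: Characterization of Tight-Binding, Cysteine-Rich Trypsin Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico characterization of cysteine-rich
    serine-peptidase inhibitors such as those found in spider digestive
    fluids: tight-binding titration kinetics (Morrison model and
    stoichiometric K_D estimation), electrospray charge-state envelope
    deconvolution to neutral mass, MALDI adduct interpretation, sequence
    physicochemistry (average and monoisotopic mass, isoelectric point,
    PEST motif scoring, peptide coverage, gel-migration mass), cysteine
    framework and disulfide-connectivity family classification (ICK,
    DDH, Kunitz, Kazal, HAND, MIT1/colipase), and hydrogen-bond geometry
    of enzyme-inhibitor structure models.  Synthetic-data generators
    with known ground truth make every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
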