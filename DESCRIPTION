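Package: dockmine
Title: Text-Mining-Derived Interface Constraints for Protein-Protein Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines biomedical abstracts for residue-level information on a
    protein-protein interaction and turns it into constraints for rigid-body
    docking. Builds boolean literature queries from protein name metadata,
    extracts amino-acid/number mentions with a regular-expression grammar,
    filters mentions against solvent-exposed residues of the target
    structures, optionally removes irrelevant abstracts with a bag-of-words
    support vector machine, ranks surviving residues by a capped confidence
    score, and rescores docking-scan matches by the summed confidence of
    constraint residues at each model interface. Includes synthetic corpus
    and toy-complex generators so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    jsonlite,
    xml2,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
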