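Package: pts2screen
Title: Proteome Screening for Type-2 Peroxisomal Targeting Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens protein sequences for type-2 peroxisomal targeting
    signals (PTS2), the N-terminal nonapeptide recognized by the PEX7
    receptor, and for C-terminal PTS1 tripeptides. Provides positional
    nonapeptide motif scanning with stringent, relaxed and custom residue
    class grammars, N-terminal window filtering, detection of the
    DEG15-type cleavage-site cysteine, BLAST tabular hit filtering under
    E-value/identity/coverage thresholds, cross-ortholog conservation
    classification with optional alignment concordance checks, and a
    synthetic proteome generator with planted signals and an exhaustive
    ground-truth oracle so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
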