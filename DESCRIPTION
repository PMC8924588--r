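Package: yaliclone
Title: In Silico Golden Gate Assembly Toolkit for Yarrowia lipolytica Pathway Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designer and simulator for a BsaI-based modular cloning (Golden
    Gate) toolkit targeted at non-homologous end-joining integration in
    Yarrowia lipolytica. Models type IIS restriction digestion with exact cut
    geometry, simulates one-pot assembly of 4, 7, or 10 fragments into the
    pGGYL1-3 destination-vector grammar with blue/white colony prediction and
    mis-join detection, removes internal BsaI/SwaI sites from coding sequences
    by codon-preserving synonymous substitution, extracts SwaI integration
    cassettes, performs in silico colony PCR and marker recycling (Cre/loxP,
    hisG-URA3-hisG pop-out), enumerates combinatorial promoter/terminator
    shuffling libraries, plans multi-round pathway builds, and tabulates
    strain-improvement metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
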