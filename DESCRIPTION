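Package: ampliplex
Title: Species-Diagnostic Multiplex PCR Design and In Silico PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for developing species-specific multiplex PCR assays from
    barcode-gene alignments (e.g. COI). Builds per-species consensus profiles
    with intraspecific polymorphic-site masks, counts discriminative nucleotide
    positions between species, enumerates primer candidates under Primer3-style
    length/Tm/GC constraints with a nearest-neighbor melting-temperature model,
    and searches for multiplex panels whose product sizes are separated enough
    to be read on an agarose gel. Includes mismatch-tolerant in-silico PCR,
    multiplex band-pattern simulation, rule-based species calling from gel band
    patterns, and a synthetic clade/cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
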