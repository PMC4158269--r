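Package: darkislands
Title: Dark-Matter Gene Islands, Integrated Elements and Attachment-Site
    Repeats in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags rare, uncharacterized ("dark matter") genes from
    ortholog-family phyletic patterns, detects and merges dark-matter
    islands along replicons by sliding-window scans, characterizes island
    protein features against length-matched backgrounds, contrasts genome
    groups such as thermophiles and mesophiles, cross-maps mobile-element
    and defense annotations onto islands, and calls integrated-element
    boundaries from tRNA- and integrase-anchored maximal perfect direct
    repeats. A synthetic multi-genome generator with emitted ground truth
    (planted islands, planted attachment-site repeats, feature
    enrichments) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
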