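Package: isomiRseq
Title: IsomiR Profiling and Differential Abundance for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles microRNA sequence variants (isomiRs) in small RNA
    sequencing libraries. Reads are adapter-trimmed, length-filtered and
    collapsed, then grouped onto canonical mature miRNAs under an ungapped
    tolerance rule (bounded end offsets plus bounded internal mismatches),
    classified against the precursor hairpin into an isomiR taxonomy
    (truncations, templated extensions, non-templated 3' tails, internal
    substitutions, shifted precursor windows), and quantified as reads per
    million mapped (RPMM) at three aggregation levels. Two-condition
    differential abundance uses a signed fold-change convention and a
    weighted beta-binomial (Baggerly-style) proportions test across
    replicate libraries. A deterministic simulator generates references,
    libraries and truth tables so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
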