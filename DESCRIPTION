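Package: codontrend
Title: Codon Usage Trends and Host Adaptation in Viral Coding Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage and amino acid
    composition across panels of viral coding regions. Computes relative
    synonymous codon usage (RSCU), Wright's effective number of codons (Nc),
    and position-specific nucleotide composition under configurable
    codon-inclusion rules; extracts compositional trends by principal
    component analysis with a deterministic sign convention and a
    correlation screen; and compares viral codon usage with host cell-type
    usage tables using Pearson correlation and the Hotelling test for two
    dependent correlation coefficients. Includes a synthetic panel generator
    emulating a monotone gradient in third-position A+T content, so the
    whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
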