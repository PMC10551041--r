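Package: crisprib
Title: Guide Design and Screen Analysis for a Thermophilic Type I-B CRISPR-Cas
    System
Version: 0.1.0
Authors@R:
    person("crisprib", "developers", email = "crisprib@example.org",
           role = c("aut", "cre"))
Description: Design tools for the thermophilic type I-B CRISPR-Cas system of
    Parageobacillus thermoglucosidasius. Scans bacterial genomes for the TTA
    protospacer-adjacent motif (PAM), designs truncated crRNAs (tgRNAs,
    spacer <= 26 nt) for transcriptional repression and full-length crRNAs
    (>= 27 nt) for Cas3-mediated cleavage and editing, builds genome-scale
    CRISPRi libraries with positional binning on the template strand, screens
    candidate spacers for off-targets under the permissive PAM set, assembles
    Golden-Gate oligos and multiplex mini-CRISPR arrays, and quantifies and
    ranks guide enrichment from pooled-screen FASTQ reads. A synthetic-data
    module generates annotated micro-genomes and spike-in screen reads so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
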