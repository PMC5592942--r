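Package: aneuscreen
Title: Aneuploidy Discovery and Causal-Interval Mapping from Yeast Genome Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mutation-accumulation screens in haploid yeast:
    simulation of genomes, mutant cohorts and sequencing pileups with known
    truth; allele-fraction thresholded calling of point mutations and small
    indels with iterative progenitor-reference refinement; detection of
    whole-chromosome disomies and terminal segmental duplications from
    windowed sequencing coverage; design of PCR-mediated chromosomal deletion
    (PCD) constructs and inference of causal intervals from truncation panels;
    and the screen's phenotype arithmetic (minimum inhibitory concentrations,
    two-stage tolerance filters, replicate summaries, and relative qPCR
    copy-number quantification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
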