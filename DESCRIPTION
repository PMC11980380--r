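Package: foramCodon
Title: Codon Usage, Compositional Bias, and Silent-Site Dinucleotide
    Analysis for Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing nucleotide composition, codon usage, and
    amino-acid usage in curated coding sequences from single-cell
    transcriptomes, motivated by the extreme silent-site compositional bias
    observed in foraminifera. Implements GC metrics at degeneracy-stratified
    sites (GC4, GC3S, GC12), Wright's effective number of codons with its
    composition-only null curve, relative synonymous codon usage, a
    site-specific synonymous dinucleotide usage (SSDU) statistic with a
    degeneracy-stratified single-nucleotide null, expression-stratified
    regressions (neutrality plots, codon frequency versus TPM) with
    Benjamini-Hochberg correction, a coverage-based curation battery for
    cross-cell contamination and misassembly, and a synthetic multi-taxon
    transcriptome generator for end-to-end testing and parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
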