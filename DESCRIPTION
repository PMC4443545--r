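Package: scarscore
Title: Genomic Scar Signatures of Homologous Recombination Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes three SNP-array-derived genomic scar signatures of
    homologous recombination deficiency -- the number of telomeric allelic
    imbalances (NtAI), large-scale state transitions (LST), and HRD-LOH --
    from allele-specific copy-number segment profiles in the style of ASCAT
    output. Also provides auxiliary chromosomal-instability metrics (wGII,
    FLOH, mutation count), DNA-index ploidy classification, cross-signature
    breakpoint overlap (Venn) analysis, cohort-level quality control and
    statistics (rank correlation, exact rank-sum tests, Fisher odds ratios),
    and a synthetic segment-profile simulator with implanted, counted scar
    events for ground-truth validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
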