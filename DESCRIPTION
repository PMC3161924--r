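Package: chromadip
Title: Heterozygous Indel and SNV Detection from Sanger Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for somatic mutation screening from capillary (Sanger)
    sequencing traces. Implements a simplified Phred-style base caller that
    reports primary and secondary peaks, detection of heterozygous
    insertions and deletions by maximizing a shift-autocorrelation score
    over the degenerate region of a mixed-allele trace (with allele
    deconvolution and position refinement from homozygous carriers),
    PolyPhred-style heterozygous SNV calling with bidirectional
    cross-validation, tumor versus matched-normal somatic classification,
    coding-effect annotation, a neutral nonsynonymous:synonymous
    expectation by exhaustive codon substitution, and cohort summary
    statistics. A synthetic chromatogram generator produces diploid traces
    as equal superpositions of two allele traces with planted variants, so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    seqinr,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
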