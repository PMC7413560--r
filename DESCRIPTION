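Package: ctgbreak
Title: Repair Outcomes of a Cas9 Double-Strand Break in a CTG Trinucleotide Repeat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and classifies repair outcomes of a SpCas9-induced
    double-strand break inside a long CTG trinucleotide repeat at a synthetic
    SUP4-like yeast locus flanked by Ty1 LTRs. Builds a coordinate-annotated
    locus calibrated to published restriction-fragment sizes, generates
    cohorts of rearranged survivor alleles under non-homologous end-joining,
    single-strand annealing and repeat-resizing pathway models, runs virtual
    restriction digest, Southern blot, and PCR assays, infers deletion
    junctions and microhomologies with a left-aligned breakpoint caller,
    assigns each survivor one of twelve rearrangement types from the assay
    evidence, quantifies break levels and end resection from (simulated) qPCR
    Ct tables, and reproduces the survival and type-distribution statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
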