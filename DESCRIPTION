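Package: ddrquant
Title: Quantification Pipelines for RNA-Processing and DNA-Damage-Response Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable, tested implementations of the quantification steps
    used to study selective mRNA splicing and nuclear export of DNA-damage
    response transcripts: nuclear/cytoplasmic RNA-FISH ratio imaging with an
    eroded nuclear mask and a surrounding cytoplasmic ring, per-nucleus
    DNA-repair focus scoring, two-channel splicing-reporter ratio scoring,
    qRT-PCR standard-curve relative quantification with splicing and export
    indices, transcript-set filtering and overlap arithmetic with FDR
    control, exhaustive k-mer motif over-representation scanning of 3' UTRs,
    and CDS codon arithmetic for nonsense variants. Every input the pipeline
    consumes can be generated synthetically with recorded ground truth, so
    all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
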