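Package: apakit
Title: Analysis Toolkit for Alternative Polyadenylation Usage Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests alternative-polyadenylation (APA) quantifications
    produced by QAPA and DaPars, unifies them into one strand-aware data
    model, and provides differential APA usage testing (Mann-Whitney,
    Kruskal-Wallis, Benjamini-Hochberg adjustment), 3'UTR
    lengthening/shortening calls, usage-expression correlation with
    regression confidence bands, APA-index-based Kaplan-Meier/log-rank
    survival analysis, polyadenylation-signal motif scanning, annotation
    track overlap, and query utilities. Includes a synthetic-data
    generator with known ground truth and a command-line interface; all
    results export as TSV/BED.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    BiocGenerics,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
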