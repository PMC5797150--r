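Package: polyphenome
Title: Substructure-Based Polyphenol Classification and Protein Interactome Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining the polyphenol-protein interactome from heterogeneous
    public-style data. Provides a substructure (SMARTS) taxonomy that classifies
    small molecules into polyphenol classes and subclasses, a deterministic
    structure-standardization pipeline with strict-stereochemistry list matching,
    parsers and evidence filters for compound-protein interaction tables in three
    dialects, hypergeometric pathway over-representation analysis with
    Benjamini-Hochberg control and a pathway-coverage criterion, food-level
    composition and enrichment-network analysis, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
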