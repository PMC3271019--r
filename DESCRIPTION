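Package: virhijack
Title: Screening Protein Families for Host-Derived Viral Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screen for viral proteins acquired from metazoan hosts by
    horizontal transfer. Filters cross-taxa protein families (UniRef-style
    sequence clusters and Pfam-style domain families) down to an analysis
    set, detects maximal viral-only clades (viral clusters) in per-family
    phylogenetic trees with normalized-depth and condensation statistics,
    quantifies architectural simplification of viral proteins (protein
    length, domain counts, terminal TAIL and inter-domain IDOL linker
    lengths, internal-domain loss), and runs the accompanying two-sample
    Kolmogorov-Smirnov, sign-enrichment and paired t tests. Includes a
    synthetic-cohort generator with planted effect sizes so the whole
    pipeline is testable without database downloads, and a pipeline driver
    producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
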