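Package: coreresponder
Title: Core Drought-Responsive Root Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of root-microbiome responses to drought
    across plant ecotypes from 16S amplicon sequence variant (ASV) count
    tables. Implements per-ecotype differential-abundance calling with exact
    Wilcoxon rank-sum tests, cross-ecotype core-responsive ASV consensus
    calling, Bray-Curtis/PCoA/PERMANOVA community analysis, Spearman
    co-occurrence network construction with topology and cohesion metrics,
    neighbor-shift (NESH) driver-taxon detection between control and drought
    networks, greedy 97 percent OTU clustering with ASV-to-isolate matching,
    and drought-tolerance phenotype screening arithmetic. Ships a synthetic
    community generator with planted effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
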