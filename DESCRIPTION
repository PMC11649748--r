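Package: famfunnel
Title: Family-Based Exome Variant Prioritization with Co-Segregation LOD
    Scoring
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Prioritizes candidate disease variants from multi-sample
    annotated exome VCFs in small autosomal-dominant kindreds.  Implements a
    segregation-aware filtering funnel (known-variant exclusion, dominant
    segregation, consequence class, population and local allele frequency,
    k-of-n pathogenicity consensus over SIFT/PolyPhen/REVEL), exact two-point
    parametric LOD scoring by full enumeration of phased two-locus genotype
    configurations, case/control carrier-frequency screening with a
    polymorphism rule, and a composite candidate ranking.  A gene-dropping
    simulator generates pedigree exome datasets with a planted causal variant
    and per-stage decoy classes for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
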