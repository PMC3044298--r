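Package: funcoreg
Title: Function-Enriched Coregulation Networks of Transcription Factors and miRNA Families
Version: 0.1.0
Authors@R: person("funcoreg", "maintainers", email = "maintainers@funcoreg.example", role = c("aut", "cre"))
Description: Discovers function-enriched coregulation between transcription
    factors and microRNA families from regulator-target edge lists. Shared
    targets of regulator pairs are profiled over Gene Ontology level-2
    biological-process terms, scored with a multivariate hypergeometric
    log-likelihood and calibrated by permutation against genome-wide null
    gene sets. Significant pairs are expanded into per-term functional
    linkages (Fisher's exact test with Benjamini-Liu or Benjamini-Hochberg
    FDR control), assembled into coregulation multigraphs, screened for
    upstream network motifs (feed-forward loops, common upstream regulators,
    upstream crosstalk) against resampled background pair sets, and
    contrasted by expression correlation between paired normal and tumour
    samples. A synthetic-data generator with planted ground truth makes the
    whole pipeline testable without external database snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
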