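Package: coexmod
Title: Co-Expression Modules and Metabolic Trait Association in Adipose
    Tissue Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds modules of co-expressed microarray probes by iterative
    greedy merging of the most strongly positively correlated probe or
    module pairs (average-linkage on Pearson correlation, stopping below a
    correlation threshold), and relates module expression profiles to
    clinical traits by Spearman rank correlation with Bonferroni
    correction and confounder-conditional partial rank correlation.
    Includes per-tissue quantile normalization and sample quality control,
    Wilcoxon Mann-Whitney differential expression between two adipose
    depots with fold-change binning and random stratified selection of
    validation candidates, hypergeometric gene-set overlap tests, network
    and heatmap exports, and a synthetic two-depot cohort generator with
    planted modules, trait couplings, confounders and tissue effects for
    validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    igraph,
    jsonlite
Config/testthat/edition: 3
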