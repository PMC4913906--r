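Package: methex
Title: Methylation QTL Mapping with LD-Aware Multiple-Testing Correction and Causal Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide methylation quantitative trait locus
    (mQTL) analysis in population cohorts: cis/trans association scans of SNP
    dosage against CpG methylation (M-values) with covariate adjustment via a
    fast residualize-then-correlate formulation, LD-tag-based Bonferroni
    correction in which the number of independent tests is counted by greedy
    pairwise tagging at a configurable r-squared threshold, eQTL follow-up of
    significant mQTL SNPs, SNP-phenotype association with sign-concordant
    external replication, a four-condition causal inference test classifying
    genotype-methylation-phenotype triples as causal, reactive or independent,
    and genomic-context enrichment of significant CpGs. Includes a synthetic
    cohort generator (LD-block genotypes, planted cis/trans effects, batch and
    covariate structure, mediation triples) so every stage is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
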