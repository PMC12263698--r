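Package: cloneflow
Title: Tumor Clone Deconvolution, Phylogeny, Mutational Signatures and
    Metastatic Migration from Bulk Sequencing Read Counts
Version: 0.1.0
Authors@R:
    person("cloneflow", "developers", email = "cloneflow@example.org",
           role = c("aut", "cre"))
Description: A single-patient tumor evolution pipeline. From per-sample
    reference/mutant read counts at somatic SNVs it deconvolutes clone
    genotypes and clone frequencies under a CNA-free heterozygous model
    (V = f M / 2), reconstructs a maximum-parsimony clone phylogeny with
    Fitch ancestral genotypes, contracts it into a mutational tree with
    driver-mutation timing, refits 96-channel SBS mutational-signature
    activities per branch by constrained least squares with
    spurious-signature filtering and neighbor-branch harmonization,
    infers a metastatic cell-migration graph from exact sum-/max-product
    posteriors of ancestral anatomical locations, and summarizes
    between-sample clone-composition similarity with weighted UniFrac and
    MNTD distances and a neighbor-joining sample tree. Includes a
    ground-truth simulator and deterministic SVG renderings of every
    result.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
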