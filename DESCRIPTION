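Package: varstruct
Title: Variant Effect Annotation and Mutation-Induced Protein Structural
    Perturbation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps coding-sequence SNPs and InDels to protein-level effects,
    builds wild-type/mutant residue correspondences across substitutions and
    in-frame indels, performs Kabsch least-squares superposition of C-alpha
    traces with optional outlier-rejection refinement, and quantifies
    mutation-induced conformational perturbation via global RMSD,
    local-window RMSD and the signed neighbor-distance change statistic
    (delta-D). Also provides genome-wide variant landscape summaries
    (strand-collapsed SNP mutation spectrum, InDel length classes, windowed
    density tracks and their association) and deterministic synthetic-data
    generators with analytic oracles for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
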