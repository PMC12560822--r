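Package: convsites
Title: Detection of Convergent Amino Acid Substitutions on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans protein alignments of single-copy orthologs for convergent
    and parallel amino acid substitutions on designated foreground lineages of
    a fixed species tree. Ancestral states are reconstructed by marginal
    maximum posterior under the JTT empirical substitution model with
    gene-specific equilibrium frequencies; the observed number of convergent
    sites per gene is compared with its analytic expectation under the same
    model through a Poisson exceedance test with Benjamini-Hochberg false
    discovery rate control. Includes a sequence simulator on phylogenies with
    controlled injection of convergent substitutions for power and calibration
    studies, and summary arithmetic for comparative genome feature tables
    (gene density, group statistics, shared positively-selected-gene
    percentages, rank-sum group contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
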