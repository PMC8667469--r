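Package: triqtl
Title: QTL Mapping in Triploid Progeny of Tetraploid x Diploid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis in triploid
    mapping populations derived from tetraploid x diploid crosses genotyped
    at low sequencing depth. Implements continuous mapping (regression of
    logit-scale adjusted trait means on per-individual allele-frequency
    estimates from read counts, with a harmonic-mean-depth correction of the
    attenuated allele-substitution effect), maximum-likelihood allele-dosage
    calling from allelic depths, classification of parental dosage
    combinations and their segregation status, simplex-marker linkage map
    construction with Haldane distances, simple and composite interval
    mapping by Haley-Knott regression, closest-gene annotation from GFF3,
    and a fully parameterised synthetic cross generator (bivalent tetraploid
    meiosis, negative-binomial depths, randomized complete block phenotypes)
    so that every stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    vcfR,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
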