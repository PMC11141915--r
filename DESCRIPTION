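Package: chromoevo
Title: Multiregion Clonal Evolution Inference for Chromophobe Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the clonal evolution of chromophobe renal
    cell carcinoma (ChRCC) from multiregion tumor sequencing data: allele-specific
    copy-number inference with joint purity/ploidy estimation from SNP log-ratio and
    allelic log-odds profiles, whole-genome-doubling and chromosome-arm calls,
    somatic mutation multiplicity, zygosity and event timing relative to genome
    doubling, driver phylogeny reconstruction from binary mutation presence
    patterns, and immunohistochemistry/expression scores. Includes a forward
    simulator of ChRCC-like clonal evolution (hypodiploid classic clones with
    recurrent monosomies, TP53-like and PTEN-like drivers, whole-genome doubling in
    dedifferentiated clones) that emits multiregion read-count observations with
    full generating truth, so every inference stage can be validated without
    access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
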