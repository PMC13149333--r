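Package: straingraft
Title: Strain Deconvolution, MHC Haplotyping and Transplantation Planning
    for Mouse Cancer Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the inbred-strain composition, MHC (H2) haplotype, sex
    and computational backcross status of mouse cancer cell lines from
    genomic SNP calls using group-specific signature SNP libraries; plans
    syngeneic transplantation experiments via a recipient-dependent
    "effective" protein-altering tumor mutational burden; and characterises
    tumor genotypes through purity-corrected Kras/Cdkn2a allele-state
    calling, CNV load, the weighted genome instability index, a 1-Mb-binned
    genome-stability distance between copy-number profiles, and
    read-count-based ranking of transposon insertion sites. Includes
    seeded generators for synthetic strain catalogs, crossed mosaic
    genomes, tumor/normal variant tables and segmented copy-number
    profiles with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
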