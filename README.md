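# straingraft

Strain deconvolution, MHC haplotyping and syngeneic transplantation
planning for mouse cancer models — plus purity-aware tumor-genotype
metrics.

## The problem

Mouse cancer cell lines are genetic mosaics. Alleles engineered in
129-derived ES cells are bred into C57BL/6 or FVB backgrounds,
backcrossing is rarely complete, and genetic linkage keeps donor-strain
haplotype blocks attached to every engineered allele. For
immunocompetent transplantation this matters twice over: residual
foreign-strain DNA and mismatched MHC (*H2*) haplotypes provoke
alloimmune rejection, and — more subtly — strain-specific *germline*
variants act like somatic mutations from the recipient's point of view,
inflating the immunogenic mutational burden in a recipient-dependent
way.

`straingraft` infers a line's immunogenetics from ordinary genomic SNP
calls and turns them into transplantation decisions:

- **Strain composition** via group-specific *signature SNPs*: strains of
  an inbred catalog are clustered into genealogically related groups
  (phi-coefficient correlation of SNP presence patterns,
  average-linkage clustering on 1 − r); a signature SNP is carried only
  within one group. Sample calls are scored in 10 Mb bins
  (`matched/expected` per group) and passing bins summed to percentages.
- **MHC haplotype** per *H2* gene cluster (K, A, E, D, Q, T; 1 Mb bins),
  combined into a full haplotype with a mosaic flag for recombinants.
- **Sex** from the chrY/autosome mapped-read ratio (male at ≥ 0.05).
- **Computational backcross status**
  `cBS = log2(2×100% / (ΣFS% − ΣAS%))`, where ΣFS% is the foreign-strain
  contribution and ΣAS% the part explained by linkage to engineered
  alleles (signature SNPs within ±25 Mb of an integration site are
  discounted; unknown sites subtract a flat 1% per allele).
- **Effective pTMB**: protein-altering (MODERATE/HIGH impact) somatic
  mutations plus catalog-tagged germline variants whose strain group the
  recipient does not carry, per Mb of the collapsed protein-coding
  exome; plus Fig-style recipient recommendation rules (prioritized /
  feasible / not recommended by the third-ranked background).
- **Allele states**: purity correction under the diploid-normal
  admixture model (`n_t = (CR·D − 2(1−ρ))/ρ`, `D = ρψ + 2(1−ρ)`), then
  fixed thresholds for mutant *Kras* (absent/dGD/HET/gain/amp/LOH, with
  iGD = {gain, amp, LOH}) and *Cdkn2a* (WT/HET/HOM); qPCR-based purity
  from non-recombined *Kras* LSL alleles for microdissected tissue.
- **CNV metrics**: CNV load (% autosomes with |log2| > 0.2), wGII, and a
  1 Mb-binned, median-smoothed, recentred genome-stability distance
  between two profiles of the same line.
- **Transposon insertion ranking**: counts-per-hundred-reads
  normalization, ≥ 10-read / ≥ 0.02 filters, per-sample ranking and
  top-10 classification of target-gene insertions.

Seeded generators (`simulateStrainCatalog`, `simulateCross`,
`simulateVariantTable`, `simulateSegments`) produce catalogs, crossed
mosaic genomes with linkage-block retention, tumor/normal variant tables
and segment profiles with machine-readable ground truth, so the whole
toolkit is testable offline.

## Worked example

A two-group catalog (C57BL/6 recipient, 129 donor-allele background), a
variant table with 26 somatic protein-altering mutations and 77
129-germline protein-altering variants, and the recipient-dependent
effective count:

```r
library(straingraft)
sim <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
    snpsPerGroup = 20000, groupNames = c("C57BL/6", "129"), seed = 1)
lib <- selectSignatureSnps(sim$catalog, sim$groups)
lib
#> SignatureLibrary [scope: genome] 40000 signature SNPs across 2 groups

vt <- simulateVariantTable(sim, nSomatic = 26, nSomaticSilent = 10,
    germlineCounts = c("129" = 77, "C57BL/6" = 40), nGermlineSilent = 15,
    depth = 60, seed = 2)
rec <- filterTmbVariants(vt$records, matchedNormal = FALSE)
ann <- annotateStrainGermline(rec, sim$catalog, sim$groups,
    lineBackgrounds = c("C57BL/6", "129"),
    mask = denseRegionMask(sim$catalog))
effectivePtmb(ann, "C57BL/6")
#> effective pTMB for recipient C57BL/6: 103 mutations (26 somatic + 77 mismatched germline)
effectivePtmb(ann, c("C57BL/6", "129"))
#> effective pTMB for recipient 129;C57BL/6: 26 mutations (26 somatic + 0 mismatched germline)
```

Into a pure C57BL/6 recipient the 77 129-germline variants are foreign
antigens and count; into a C57BL/6;129-F1 hybrid they are self and drop
out — the donor line's immunogenic burden is a property of the pairing,
not of the line.

Backcross status of a 4-generation backcross with realized residual 129
DNA:

```r
bc <- simulateCross(sim, "C57BL/6_S1", "129_S1",
    schedule = "backcross", nBackcross = 4, seed = 2)
strainComposition(binEnrichment(bc$calls, lib))
#>     group     length    percent
#> 1 C57BL/6 2586671812 99.2700796
#> 2     129   19019473  0.7299204
estimateBackcross(bc$calls, lib, recipientGroup = "C57BL/6")
#> foreign strain contribution: 0.73%
#> allele-clustered contribution: 0.00%
#> cBS = 8.10
```

Allele-state calls at printed thresholds:

```r
classifyKrasState(c(0.5, 0.7), c(1.0, 3.0))
#>   state dosage
#> 1   HET    HET
#> 2   amp    iGD
```

See `vignettes/straingraft-methods.Rmd` for the models, parameter
defaults and their rationale, and known limitations.

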