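---
title: "Methods: strain deconvolution, transplantation planning and tumor genotype metrics"
author: "straingraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain deconvolution, transplantation planning and tumor genotype metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straingraft)
```

# Scope

Genetically engineered mouse cancer models and the cell lines derived from
them are genetic mosaics: alleles engineered in 129-derived ES cells are
bred into C57BL/6 or FVB backgrounds, backcrossing is rarely complete, and
linkage drags donor-strain chromatin along with every engineered allele.
For syngeneic transplantation, immunophenotype is destiny — a residual
129 haplotype block, a mismatched MHC (*H2*) cluster, or a male-specific
antigen can turn a "syngeneic" graft into an alloimmune experiment.

`straingraft` infers these properties from ordinary genomic SNP calls and
turns them into transplantation decisions. It covers five method groups:

1. **Signature-SNP libraries** from an inbred-strain variant catalog, and
   binned-enrichment **strain composition**, **MHC haplotype**, **sex**,
   and **computational backcross status (cBS)** of a sample.
2. **Effective protein-altering tumor mutational burden (pTMB)** for a
   chosen transplantation recipient, and recipient recommendation rules.
3. **Purity-corrected allele states** of mutant *Kras* and of *Cdkn2a*.
4. **Copy-number metrics**: CNV load, the weighted genome instability
   index (wGII), and a binned genome-stability distance between two
   profiles of the same line.
5. **Transposon insertion ranking** as a read-out of selective advantage.

A sixth group, the synthetic-data generators, exists so that every method
is testable against known ground truth without any external download.

# Signature SNPs and strain composition

## The library

Every strain of an inbred panel is encoded as a presence/absence vector
over the union of catalog SNP sites (site = chromosome, position,
alternate base; different alternate bases are different sites). Pairwise
Pearson correlation of these binary vectors (the phi coefficient) feeds
average-linkage hierarchical clustering on the distance $1 - r$; cutting
the tree partitions the panel into genealogically related strain groups.
A **signature SNP** of group $G$ is a site carried by at least one member
of $G$ and by no strain outside $G$ — sharing within a group is expected
(related strains share ancestry) and explicitly allowed.

Inbred strains are essentially homozygous, so presence/absence (with
heterozygous catalog entries counted as presence) is the right resolution;
the method never distinguishes heterozygous from homozygous carriage in
the sample either, which is a documented limitation (an F1 and a
homozygous mixture read the same).

Tunables: `linkageMethod` (default `"average"`) and `cutHeight` (default
0.5 on the $1-r$ scale). Neither is dictated by first principles; on a
full-scale inbred panel the cut is a *calibration* choice — it is exposed
precisely so the library can be tuned to a reference panel's known group
structure. Group labels are deterministic (alphabetically first member).

## MHC (H2) clusters

The MHC locus on chromosome 17 is treated as six gene clusters (*H2-K,
-A, -E, -D, -Q, -T*), shipped as an editable GRCm38 interval
configuration (`mhcClusterSpec()`; coordinates approximate, intervals
non-overlapping and ordered). The whole library workflow is repeated
per cluster on the cluster-restricted catalog, yielding per-cluster
haplotype groups and cluster-scoped signature SNPs. Degenerate clusters
are handled explicitly: no catalog sites means *unresolvable*; a single
haplotype group means an empty (uninformative) library, because a
signature discriminates between groups and one group leaves nothing to
discriminate.

## Binned enrichment and composition

Sample SNP calls are matched against the library in consecutive genomic
bins (10 Mb genome-wide; 1 Mb inside MHC clusters). Per bin and group,
`expected` is the number of library sites in the bin, `matched` the
subset also called in the sample, and the enrichment score
`matched/expected`. Two guards apply before a bin contributes to the
composition: at least `minExpected = 5` expected sites (sparse bins carry
no information) and a score of at least `minScore = 0.3` (a "sufficient"
enrichment; scores from variant-calling noise are far lower, scores from
a true haplotype on either one or both chromosomes are far higher).

Passing bins are summed per group, **weighted by their score**, and
normalized across groups to percentages. The weighting is this package's
design choice where the summation basis was genuinely open: counting
whole bins overestimates residual linkage blocks that only partially
cover a bin (a 9 Mb block would read as 20 Mb), which biases the
backcross status; score weighting is unbiased for partial blocks and
changes nothing for pure inbred lines (100%) or F1 hybrids (50/50).
Because the denominator is the sum over groups, not genome length, the
percentages always sum to 100 where defined.

## Sex

The ratio of Y-chromosome uniquely mapped reads over the sum of
autosomal reads calls male at $\ge 0.05$ and female below; the call is
invariant under uniform scaling of all counts, and a missing Y count is
treated as 0 with a warning.

## Backcross status

The backcross generation is estimated as

$$\mathrm{cBS} = \log_2\!\left(\frac{2 \times 100\%}{\sum \mathrm{FS}\% - \sum \mathrm{AS}\%}\right)$$

where $\sum \mathrm{FS}\%$ is the total non-recipient (foreign) strain
contribution and $\sum \mathrm{AS}\%$ the part of it attributable to
linkage with engineered alleles. Each backcross halves the foreign
contribution, and the factor 2 accounts for both chromosomes of the
diploid genome. For every allele with a known integration site, the
origin group's signature SNPs within a 25 Mb window of the site are
removed and the composition recomputed on the *unadjusted* denominator,
so the drop is exactly the removed linkage contribution; the window is
applied symmetrically (±25 Mb), an interpretation the interface exposes
via `window`. Alleles with unknown integration sites subtract a flat 1%
from their origin background instead, bounded by what that background
actually contributes. An adjusted foreign contribution at or below 0.1%
— or a cBS at or above the reporting cap of 10 — is reported as the
*fully backcrossed* sentinel rather than an unstable logarithm.

# Effective pTMB and recipient recommendation

Mutational-burden variants pass fixed read-support filters, all
inclusive: coverage ≥ 10 in tumor (and matched normal where present),
VAF ≥ 10%, ≥ 3 variant-supporting tumor reads, and — only with a
matched normal — zero variant-supporting normal reads. For the
*effective* pTMB the normal-presence filter is deliberately not applied,
because germline variants are the point: variants are instead split into
somatic (tumor only) and germline (tumor and normal), and only
protein-altering variants (predicted impact MODERATE or HIGH) count.

A germline variant is tagged with a strain group when all three hold:
it is reported in the strain catalog, its carrier group is among the
line's annotated backgrounds, and it lies outside SNP-dense regions.
The dense-region mask tiles the genome into 10 kb windows and masks
windows exceeding 5× the median catalog SNP count over covered windows
(such pile-ups indicate assembly problems rather than real variation);
both window and factor are exposed.

For a recipient with background groups $R$ (an F1 hybrid contributes
both parents), the effective set is

$$\text{effective} = \text{somatic} \;\cup\; \{\text{tagged germline}: \text{tag} \notin R\},$$

so a germline variant matching the recipient is a self-antigen there and
drops out. Counts are reported absolutely and per Mb of the collapsed
protein-coding exome (exons of protein-coding transcripts, overlaps
merged, strands unioned).

Recommendation rules rank the line's backgrounds by percent: a third
background below 1% (or absent) is *prioritized*, 1–9% *feasible*, and
≥ 10% *not recommended* (no single recipient or F1 can match three
dominant backgrounds). Candidates are the top strain and, when a second
background contributes ≥ 1%, the matched F1 hybrid; candidates that do
not cover the line's resolved MHC cluster calls are dropped, and male
lines carry a male-recipient constraint (male-specific antigens
mismatch into female hosts).

# Allele states under purity

Bulk tissue dilutes tumor signal with stroma. With tumor cell fraction
$\rho$ and tumor ploidy $\psi$ (curated purity/ploidy solutions are
*consumed*, never estimated here), an admixed cell averages
$D = \rho\psi + 2(1-\rho)$ genome copies, so a locus observed at copy
ratio $\mathrm{CR}$ has tumor local total copy number
$n_t = (\mathrm{CR}\,D - 2(1-\rho))/\rho$, pure copy ratio $n_t/\psi$,
and — assuming the variant is absent from normal cells — pure VAF
$\mathrm{VAF}\,(\rho n_t + 2(1-\rho))/(\rho n_t)$, clamped to $[0,1]$.
This is the standard diploid-normal admixture model; $n_t \le 0$ flags
the homozygous-deletion regime, where a VAF correction is meaningless
and reported missing. Samples below 20% purity are excluded from
allele-state calling altogether: allelic imbalance cannot be resolved
reliably at that tumor content.

The classifiers then apply fixed thresholds to the purity-adjusted
values. Mutant *Kras*: absent (VAF < 0.05), dGD (0.05 ≤ VAF < 0.4),
HET (0.4 ≤ VAF < 0.61), and for VAF ≥ 0.61 LOH (CR < 1.3), gain
(1.3 ≤ CR < 2.8) or amp (CR ≥ 2.8); the dosage category iGD comprises
gain, amp and LOH (all increase the mutant-allele dose — this mapping is
exposed rather than hard-wired into downstream counts). *Cdkn2a*: HOM
(VAF ≥ 0.85 or CR ≤ 0.19), else HET (0 < VAF < 0.85 or
0.19 < CR < 0.87), else WT; the clauses overlap as printed, and the
precedence HOM > HET > WT resolves every point of the (VAF, CR) plane to
exactly one state. The *Cdkn2a* VAF input is the maximum VAF over
detected inactivating mutations, 0 for pure copy-loss cases.

For microdissected tissue carrying a conditional *Kras* LSL allele, the
qPCR route estimates purity directly: tumor cells have recombined the
Lox-Stop-Lox cassette away, stroma is heterozygous for it, so the
LSL/locus-copy ratio — calibrated against a known-heterozygous control —
*is* the stroma copy fraction $s$, and purity is $1-s$. Amplicon VAFs
are then corrected by subtracting stroma reads:
$\mathrm{VAF}_{\mathrm{pure}} = (\mathrm{VAF} - s f_{\mathrm{mut}})/(1-s)$,
with $f_{\mathrm{mut}} = 0.5$ by default because heterozygous stroma
still reads the mutant base from the non-recombined cassette allele at a
genomic amplicon; assays in which the cassette disrupts the amplicon
should set 0. This correction is the exact inverse of its forward
mixture model for all valid $(s, f_{\mathrm{mut}})$.

# Copy-number metrics

Segments are consumed as (chrom, start, end, log2) tables; nothing is
re-segmented.

- **CNV load**: percent of the autosomal genome (mouse chr1–19, human
  chr1–22 by build) in segments with $|\log_2| > 0.2$; strictly greater,
  segments clipped to chromosome ends with a warning. Splitting a
  segment changes nothing.
- **wGII**: the sample median copy state is the length-weighted median
  of autosomal log2 values; each autosome contributes the fraction of
  its covered length deviating from that median by more than a
  tolerance, and wGII is the mean of those fractions. The tolerance
  reuses the 0.2 log2 cutoff by default and is configurable, since the
  canonical deviation band is a choice, not a law.
- **Stability distance** between two profiles of the same line (e.g.
  WES vs low-coverage WGS replicates years apart): both profiles are
  binned to 1 Mb (overlap-length-weighted mean per bin; uncovered bins
  stay missing — no imputation), smoothed per chromosome with a
  centered, edge-truncated running median of 5 bins (chromosomes the
  user flags for chromothripsis or other complex rearrangements are
  skipped), and recentred by subtracting the genome-wide median of the
  smoothed bins when that median is positive — applied independently
  per profile, so a global platform offset cancels. The distance is the
  per-bin absolute difference, averaged per chromosome over bins present
  in both profiles, then averaged over chromosomes. On recentred
  profiles this is a pseudometric: symmetric, zero on identical input,
  and triangle-consistent per bin.

# Insertion ranking

Transposon insertion read counts are normalized to counts per hundred
reads (raw/total × 100); insertions under 0.02 are noise and removed.
Ranking drops sites with fewer than 10 supporting reads or normalized
counts under 0.02 and orders the rest per sample by normalized count,
ties by raw reads, then position — normalized-count-primary ordering is
the package's resolution of the open weighting question and is
configurable by reordering the inputs. Insertions in target regions
(supplied as BED, e.g. the *Cdkn2a* locus or WNT pathway genes; no gene
models are hard-coded) are classified high-ranked when within the top
10 of their sample; the cohort fraction of high-ranked target
insertions is a direct read-out of the selective advantage the
perturbation conferred during tumor evolution.

# Synthetic data: what it does and does not emulate

All generators are deterministic functions of their parameters and seed.

- `simulateStrainCatalog()` plants group-private SNP pools (uniform
  placement on the mm10 chromosome arms, optional region restriction for
  MHC work) with a within-group sharing probability; the pools *are* the
  signature truth.
- `simulateCross()` builds diploid mosaic genomes for F1s, backcrosses
  and homozygous single-crossover MHC recombinants. Meioses draw
  Poisson(0.5) crossovers per chromosome at uniform positions — a flat
  genetic map, sufficient for linkage-block behavior without a real map.
  Engineered alleles model breeder selection: gametes are redrawn until
  the origin-strain block containing the integration site is retained,
  which is exactly why such blocks "withstand" backcrossing. Realized
  per-group fractions are reported presence-based (fraction of genome
  where a group is present on ≥ 1 haplotype, normalized across groups)
  because the SNP-pattern method is presence-based; raw diploid
  fractions are returned alongside.
- `simulateVariantTable()` separates tumor-only somatic from
  tumor-and-normal germline records with binomial (optionally
  deterministic) read depths and exact protein-altering counts;
  germline records are drawn from catalog sites so the tagging
  machinery is exercised end to end.
- `simulateSegments()` plants copy-number events on a flat baseline and
  emits a replicate with per-segment noise and an optional global
  offset, emulating two platforms profiling one sample.

Not emulated: sequencing errors and false-positive SNP calls, reference
bias, non-uniform recombination, de novo mutation, subclonality, and
real catalog linkage structure. Passing tests therefore demonstrate the
machinery is correct and recovers planted truth under clean conditions;
they do not certify calibration on real panels, which is what the
exposed `cutHeight`, `minScore` and mask parameters are for.

Test problem sizes are deliberately desk-scale and stated here as the
package's own choice: two-group catalogs of 20,000 SNPs per group
(≈ 74 expected signature SNPs per 10 Mb bin) for composition and cBS
recovery over 20 seeded crosses, 2,000 MHC-region SNPs per group
(≥ 50 informative signature SNPs per cluster and group) for 60 seeded
mosaic-detection runs, and 0.01-step grids for the classifier oracles.

# Numerical choices and degenerate inputs

- Coordinates are 1-based closed internally (the GRanges convention);
  BED-style half-open inputs are converted at the boundary.
- Ties in composition ranking break by descending percent then group
  name; in insertion ranking by raw reads then position. Group labels
  come from the alphabetically first member strain.
- Clamps: adjusted VAFs to $[0,1]$; negative allele-clustered
  adjustments to 0 with a warning; stroma fraction to $[0,1]$.
- Degenerate inputs: strains with no (or all) sites are excluded from
  correlation with a warning; empty signature libraries are legal;
  empty call sets score 0 with a warning; chromosomes without segments
  are excluded from wGII with a warning; zero shared bins omit the
  chromosome from the stability distance.

# Known limitations

- **Sub-bin linkage blocks evade detection.** A foreign block covering
  less than ~30% of a 10 Mb bin scores below the 0.3 sufficiency gate
  and contributes nothing; residual blocks of 2–6 Mb can therefore be
  missed entirely, which *overestimates* cBS. Seeded-simulation tests
  show this is the dominant error mode of backcross estimation.
- Presence-based analysis cannot distinguish heterozygous from
  homozygous carriage, nor an F1 from a 50/50 cell mixture.
- Purity/ploidy solutions and chromothripsis exclusion lists are inputs:
  expert curation is consumed, not replaced.
- The MHC cluster coordinates are an editable approximation; boundary
  SNPs near cluster edges belong to whichever configured interval
  contains them.
- No lift-over, no imputation, no pedigree reconstruction beyond the
  cBS scalar.

# A compact worked example

```{r example}
set.seed(1)
sim <- simulateStrainCatalog(nGroups = 2, strainsPerGroup = 2,
    snpsPerGroup = 20000, groupNames = c("C57BL/6", "129"), seed = 1)
lib <- selectSignatureSnps(sim$catalog, sim$groups)
lib

bc <- simulateCross(sim, "C57BL/6_S1", "129_S1", schedule = "backcross",
    nBackcross = 4, seed = 2)
comp <- strainComposition(binEnrichment(bc$calls, lib))
head(comp, 3)

estimateBackcross(bc$calls, lib, recipientGroup = "C57BL/6")
backcrossStatus(max(bc$foreignPercent, 1e-9))$cbs  # truth for comparison
```
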