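---
title: "Identifying breed-specific SNPs in multi-breed genotype panels"
author: "breedmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying breed-specific SNPs in multi-breed genotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedmark)
```

## The problem

Conservation and breeding programmes for native livestock populations —
the motivating case is the Korean native pig breeds (Jeju native pig JNP,
Korean native pig KNP, and the Korean wild boar KWB) alongside western
commercial breeds — need markers that separate one population from all
others. A *breed-specific SNP* is a biallelic variant at which one allele
is (nearly) fixed in the target breed while the complementary allele is
(nearly) fixed everywhere else. Such markers are breed-informative: they
support breed assignment, traceability, and hypotheses about the genomic
basis of breed characteristics when they fall in coding sequence.

`breedmark` implements the full desk-side pipeline: reading multi-sample
VCF genotypes, MAF/HWE quality control, the allele-frequency classifier,
synonymous/nonsynonymous consequence annotation from FASTA + GFF3,
population-structure verification (GRM-based PCA and neighbor-joining
trees), gene-set over-representation, descriptive reports, and a synthetic
multi-breed generator that plants known breed-private alleles so every
stage can be validated against ground truth.

## The classifier

For a target ("object") breed $O$ with pooled background breeds $B$, and
an allele $A' \in \{\mathrm{ref}, \mathrm{alt}\}$ with complement $A$, a
site is breed-specific for $O$ when

$$
\frac{\#A' \text{ alleles in } O}{\#\text{called alleles in } O} > t
\quad\text{and}\quad
\frac{\#A \text{ alleles in } B}{\#\text{called alleles in } B} > t,
\qquad t = 0.9 .
$$

Both orientations are tested at every site; because $t > 0.5$ at most one
can hold. Design points worth making explicit:

* **Strict inequality.** A frequency of exactly 0.9 does *not* qualify.
  With 6 diploid samples (12 alleles) the rule is therefore exactly "at
  least 11 of 12 called alleles", which the test suite asserts as an
  integer identity.
* **Denominator under missingness.** "Total allele count" is read as the
  *called* (non-missing) alleles of the population. This is the only
  reading that keeps the criterion well-defined at sites with missing
  genotypes; missing alleles contribute to neither numerator nor
  denominator. A site where either population has no called allele is
  never specific.
* **Low-confidence flag.** When fewer than half of a population's alleles
  are called at a site the call is still made but flagged
  `low_confidence`, so a handful of genotyped samples cannot silently
  decide specificity.
* **Background exclusions.** Native breeds can share recent ancestry with
  a wild population; alleles private to the native-plus-wild clade would
  otherwise be masked. `native_breed_configs()` therefore builds, for each
  native target, a background of all breeds *minus the target and minus
  the wild breed*, while the wild target itself is contrasted against all
  other breeds. Only the wild breed is excluded by default — fellow native
  breeds stay in each other's backgrounds — but
  `breed_specific_config()` accepts any exclusion set.
* **Raw genotypes by default.** The classifier is designed to run on
  pre-QC genotypes; QC is applied to the panels used for
  population-structure figures. Both stages accept either panel, so the
  order is a user choice, not a constraint.
* **Admixed individuals** are removed with an explicit drop-list
  (`drop_samples()`) before classification. Detecting admixture is out of
  scope; it is an upstream analysis with dedicated tools.

Variant identity throughout is the `(chrom, pos, ref, alt)` tuple —
rs identifiers are unreliable keys for novel variants and are used only
for the rs-tagged/novel descriptive split.

## Quality control

`apply_qc()` implements two composable site filters, computed on the whole
panel with all breeds pooled (per-breed QC is deliberately not offered, as
the classifier itself is the per-breed analysis):

* **MAF**: sites with minor allele frequency strictly below `maf_min`
  (default 0.05) are removed; an undefined MAF (no called genotypes)
  also removes the site. The boundary is kept.
* **HWE**: the two-sided exact conditional test. Given the observed allele
  counts, the p-value sums the probabilities of all heterozygote counts
  whose conditional probability does not exceed the observed one,
  computed by the standard probability-ratio recurrence. The default
  threshold is `1e-6`, strict. The exact test was chosen over the
  chi-square approximation because per-breed sample sizes in this setting
  are small (down to 6); a mid-p variant is available but off by default.
  The test equals exhaustive enumeration to below `1e-12` for every
  genotype tally up to 50 samples (asserted in the suite), and its
  empirical rejection rate on data simulated under HWE is conservative.

Imputation is not re-implemented: missingness is carried through every
stage with pairwise-complete handling, and the effect of that choice is
visible in the per-pair counts the GRM and p-distance report.

## Consequence annotation

`annotate_variant()` is a minimal SNV-only consequence annotator over
user-supplied gene models (GFF3 CDS features + reference FASTA): it
locates the affected codon strand-aware, substitutes the alternative base
(complemented on the minus strand), translates both codons with the
standard genetic code, and reports one of six consequences — `intergenic`,
`non_coding_gene_region`, `synonymous`, `nonsynonymous`, `stop_gained`,
`stop_lost`. The richer ontology of full annotators (splice classes, UTR
subtypes, multi-transcript ranking) is deliberately collapsed: downstream
analysis only needs the protein-changing/neutral distinction, with
stop-gain/loss reported separately because whether they count as
"nonsynonymous" varies between tools. One transcript per gene is kept (the
longest CDS); models whose CDS length is not a multiple of 3 are skipped
with a warning. The reference base is checked against the VCF REF allele
and a mismatch is a hard data-integrity error.

The correctness argument is dual-route: the test suite re-derives every
annotation by substituting the base into the *full* coding sequence and
translating whole proteins, a path that shares no code with the
codon-local classifier.

`breed_specific_nssnps()` intersects classifier output with annotations
(stop-gain/loss included, reported by category), and `genes_hit()` has two
modes mirroring two downstream uses: `"nssnp"` (genes with a
protein-changing breed-specific SNP) and `"all"` (genes whose bounds
contain any breed-specific SNP, useful when a breed yields too few nsSNPs
for enrichment).

## Population structure

* `compute_grm()` is the standard GRM estimator
  $G_{jk} = \frac{1}{M}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$
  with $p_i$ estimated from the full panel (all breeds pooled — per-breed
  frequencies would change the PCs), monomorphic sites skipped, and $M$
  counted per pair over sites called in both samples.
* `grm_pca()` eigendecomposes the GRM; coordinates are eigenvectors scaled
  by $\sqrt{\lambda}$. The eigenvalue sum equals the GRM trace to
  numerical precision.
* `p_distance()` is the proportion of differing alleles over shared called
  sites, in $[0,1]$.
* `neighbor_joining()` is the Saitou–Nei agglomeration on that matrix.
  A negative branch length at a join is clamped to zero with the deficit
  moved to the sister branch, preserving the joined pair's path length;
  ties in the Q-criterion break deterministically on the first minimum.
  On additive matrices the algorithm is exact, which the suite checks
  against both the input distances and an independent NJ implementation
  (`ape::nj`).

## Gene-set over-representation

`enrich()` tests a gene list against user-supplied GMT gene sets over an
explicit background universe: upper-tail hypergeometric p-value, the
conservative EASE variant (the same tail computed with one gene removed
from the overlap, so an overlap of 1 scores 1), and fold enrichment
$(k/n)\,/\,(K/N)$. Raw p-values are reported by default —
Benjamini–Hochberg is available but off — because small candidate lists
and curated term tables are conventionally read on raw p in this
literature. No annotation database is bundled: published term tables
derive from specific database snapshots and backgrounds that cannot be
reproduced faithfully, so the background is always an explicit argument.

## The synthetic generator

`simulate_panel()` emulates the statistical structure the classifier
exploits, not sequence-level realism:

* **Design.** Eight breeds with sample sizes 10/20/20/6/10/13/15/12
  (BKS, DUR, JNP, KNP, KWB, LDR, YKS, YMP) — the sampling design of the
  motivating multi-breed WGS panel, with KNP's $n=6$ deliberately kept as
  the hard small-sample case.
* **Drift.** Balding–Nichols: ancestral frequency
  $p_0 \sim U(0.05, 0.95)$, per-breed frequency
  $\mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ with $F = 0.2$ by default —
  strong enough drift that breeds are distinct, matching the observed
  clear breed separation in livestock WGS panels, while keeping incidental
  (non-planted) specific sites rare. $F = 0$ is accepted and means no
  drift (the null for false-positive accounting). The Beta variance
  $p_0(1-p_0)F$ is asserted empirically in the suite.
* **Planted truth.** 50 sites per native target breed, disjoint across
  targets, at frequency 1.0 in the target and 0.0 elsewhere — fixation /
  absence, the cleanest constructible truth. A weaker 0.95/0.05 scenario
  can be configured to exercise near-threshold behaviour.
* **Genotypes** are Binomial(2, p) within breed (HWE within breed), with
  i.i.d. missingness (default 5%, a typical post-calling missing rate) and
  optional allele-level admixture toward a donor breed.
* **Determinism.** Every output is reproducible bit-for-bit from the
  scenario seed; the suite asserts byte-identical VCFs across re-runs.

`simulate_genome()` builds small chromosomes with non-overlapping
single-exon ORFs on both strands (ATG, sense codons, stop), and
`place_planted_variants()` relocates planted sites to positions whose
consequence is *verified by the annotator itself* (a requested fraction
nonsynonymous, the rest synonymous or intergenic), giving exact truth for
the effects stage. Balding–Nichols was chosen over coalescent simulation
because it parameterizes exactly the between-breed drift the classifier
exploits and runs in milliseconds; recombination maps, linkage and
realistic demography are consciously absent, so passing tests demonstrate
correctness of the computations, not calibration on real pig data.

## Problem sizes and numerical choices

The validation suite and the acceptance script run, as the package's own
choice of problem size: the full default scenario (106 samples, 10,000
background + 150 planted sites) for recovery, Venn-structure, monophyly
and PCA checks; a 10,000-site no-drift null for false positives;
exhaustive HWE enumeration for all tallies up to 50 samples plus a
10,000-replicate conservatism simulation; 1,000 random coding SNVs for the
translation oracle; 200 random additive trees (4–8 leaves, path-length
agreement to $10^{-9}$); dense hypergeometric/EASE grids (exhaustive to
background 40, sampled to 200); and a complete pipeline re-run compared
byte-for-byte. Numerical tie-breaks: HWE configuration inclusion uses a
relative $1+10^{-10}$ tolerance on "probability not exceeding the
observed"; NJ takes the first minimal Q-pair; PCA eigenvalue signs are
arbitrary and never asserted.

## Known limitations

* Biallelic SNVs only; multiallelic records are dropped (the criterion is
  stated for one reference/alternative pair), indels and SVs are out of
  scope.
* Strictly diploid genotypes; any other ploidy is a hard error.
* Half-called genotypes (`./1`) are conservatively treated as missing.
* The annotator handles SNVs in single- or multi-exon CDS but not splice
  or regulatory effects, and uses the standard nuclear code only.
* Gene-set results depend entirely on the user-supplied sets and
  background; no database is bundled.
* Sensitivity/false-positive results on synthetic panels bound what the
  method does under its own model assumptions (independent drifting sites,
  HWE within breed); linked or selected real-data sites can behave
  differently.
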