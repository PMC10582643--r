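---
title: "Methods: VAF distances, Ward.D2 clustering, sex genotyping and hybrid parentage in amplicon panels"
author: "amplitax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAF distances, Ward.D2 clustering, sex genotyping and hybrid parentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data

Poplars of sections *Aigeiros* and *Tacamahaca* hybridize freely; cultivated
accessions are very often interspecific hybrids whose morphology is
ambiguous. A practical molecular approach is a targeted amplicon panel:
14 loci traditionally used in poplar phylogenetics — two multicopy nuclear
loci (NTS 5S rDNA, ITS), nine single-copy nuclear loci (*DSH 2*, *DSH 5*,
*DSH 8*, *DSH 12*, *DSH 29*, *6*, *15*, *16*, *X18*) and three chloroplast
loci (*trnG-psbK-psbI*, *rps2-rpoC2*, *rpoC2-rpoC1*) — plus the
sex-determining region (SDR) of chromosome 19 and the *ARR17* gene, each
sequenced to a depth of roughly 500 reads per amplicon per sample.

`amplitax` starts where variant calling ends: multi-sample VCFs with
per-sample allelic depths (`AD`). Everything upstream (trimming, mapping,
calling) is out of scope.

The central idea is to work in the coordinate system of **variant allele
frequencies** (VAF). For an alternate allele at a site,

$$\mathrm{VAF} = \frac{\text{alt reads}}{\text{ref reads} + \sum \text{alt reads}}.$$

VAF vectors capture heterozygosity directly: an F1 hybrid of two species
fixed for different alleles sits at VAF ≈ 0.5, exactly between its parents
at 0 and 1. This is why VAF distances resolve hybrids that discrete genotype
calls blur. Multiallelic sites are decomposed into one column per alternate
allele, with the full site depth in the denominator; InDel alleles are
treated exactly like SNV alleles.

## Distances

For samples $a, b$ over $M$ variant-allele columns of which $m_{ab}$ are
observed in both,

$$d(a,b) = \sqrt{\frac{M}{m_{ab}} \sum_{j \in \text{shared}} (v_{aj} - v_{bj})^2}.$$

With complete data this is plain Euclidean distance. The $M/m_{ab}$
rescaling (the same convention `stats::dist` uses) keeps distances
comparable between pairs with different amounts of missing data; a pair with
no shared columns is reported `NA` and — for clustering only — imputed by
the maximum observed distance, with a warning. Values are missing when the
site depth falls below `minSiteDepth` (default 20 reads), when a sample is
coverage-excluded for a locus group (mean group depth below `minMeanDepth`,
default 20 — a conservative fraction of the ~500-read mean), or when the
sample was absent from a source file. No per-locus reweighting is applied
when concatenating groups of unequal column counts; that is a documented
limitation, and the named locus sets (`traditional14`, `nuclear11`,
`chloroplast3`, `sdr`, `arr17`, `all16`) each get their own matrix instead.

## Clustering

Samples are agglomerated with Ward's D2 criterion applied to the distance
matrix: squared distances follow the Lance–Williams update

$$d(k, i \cup j)^2 = \frac{(n_i + n_k)\,d(k,i)^2 + (n_j + n_k)\,d(k,j)^2 - n_k\,d(i,j)^2}{n_i + n_j + n_k},$$

with merge heights reported on the distance scale. The implementation
delegates to `stats::hclust(method = "ward.D2")`; the test suite verifies it
against an independent from-scratch Lance–Williams agglomerator (merge order
and heights to 1e-9) and against the closed-form three-point example
(heights 1 and $\sqrt{27}$). Trees are exported as ultrametric Newick with
each child of a merge at height $h$ hanging at depth $h/2$, so the
leaf-to-leaf path through a node equals its merge height.

Bootstrap support is deliberately **not** computed. Most accessions are
hybrids with genuine affinity to two or more parental clusters; under
subsampling they hop between those clusters, so bootstrap frequencies
measure hybridity, not unreliability. The distance matrices themselves are
exported for inspection instead.

## Sex genotyping

In these XY poplars, a portion of the SDR carrying partial *ARR17* repeats
is present only in males. Two independent evidence lines are combined:

1. **Coverage**: a sample is male if its mean depth over the male-specific
   amplicons is at least `presenceRatioMin` (default 0.1) of its overall
   mean amplicon depth. Presence at ~full depth versus a noise floor of a
   few stray reads makes this threshold uncritical across two orders of
   magnitude.
2. **SDR clustering**: a two-way cut of the SDR tree, with each cluster
   voted by the majority of samples of known sex.

Agreement gives the call; disagreement gives `unknown`; absent labels or
coverage reduce to the available line. Using evidence-based calls rather
than reading the dendrogram by eye removes the visual-inspection step while
reproducing the same male/female split.

## Parentage of hybrids

The chloroplast is maternally inherited, the Y paternally. For a hybrid
taxon and a declared set of candidate parents (candidates are hypotheses,
not discovered automatically):

- **maternal** = argmin over candidates of the mean chloroplast-locus
  distance between hybrid and candidate samples;
- **paternal** = argmin over candidates of the mean SDR distance computed
  among male-called samples only (sons carry the father's Y; the
  male-specific SDR portion is what makes this comparison asymmetric).

Ties within 1e-9 return `undecided` — a deterministic floating-point
guard, not a biological statement. The margin (runner-up minus winner) is
reported with every call, and the degenerate case where both lineages pick
the same taxon is flagged as a non-hybrid pattern. For hybrids beyond F1,
the argmin identifies nearest lineages only; no quantitative multi-parent
decomposition is attempted.

## Consensus assignment

An accession of uncertain affiliation is assigned by requiring agreement
across locus sets (default `all16`, `sdr`, `traditional14`). Per set, the
tree is cut at the smallest $k$ at which every reference taxon is the
majority of some cluster, capped at $2T + 2$ for $T$ reference taxa; the cap
is doubled relative to the naive $T + 2$ because on sex-linked locus sets
each taxon legitimately splits into a male and a female clade, so up to $2T$
clusters may be needed before every taxon is pure. If the query's cluster
has a tied or empty majority at that cut, the cut is escalated toward the
cap until the candidate resolves — the same purity principle, kept
deterministic. The consensus label is emitted only under unanimity of the
sets in which the query is present; anything else is `ambiguous`, with
per-set candidates listed. This operationalizes "being in the taxon's
cluster" without eyeballing dendrograms, and is this package's own rule.

## The synthetic panel generator

The generator exists so that every downstream stage is testable without any
download. It emulates, per species, population alternate-allele frequencies
over the panel: a site is interspecifically variable with probability
$f = \min(1, d/q(n))$, where $d$ is the divergence parameter and $q(n)$ the
chance a random species bipartition separates a given pair; at variable
sites species are fixed 0/1 along the bipartition, so the expected per-pair
mean $|{\Delta}\mathrm{freq}|$ over sites equals $d$ (attainable up to
$q(n)$; $q = 1$ for two species). Non-variable sites share a baseline, drawn
intermediate for the multicopy loci — paralog mixtures are folded into the
allele frequency, since the analysis consumes only VAF and copy-number
mechanics are irrelevant to it. Every species pair is guaranteed at least
one diagnostic site per amplicon, and all diagnostic sites are recorded in a
truth table.

Pedigrees: a "species" sample draws both gametes from one profile; an F1
draws one allele per site from each parent (so diagnostic-site dosage is
exactly 0.5), copies the mother's chloroplast haplotype, and carries
maternal X plus paternal X (daughters) or paternal Y (sons). The SDR locus
is simulated as two amplicons, mirroring the region's structure: a shared
region present in both sexes and a male-specific region carrying the partial
*ARR17* repeats, which (like the *ARR17* amplicon) yields reads only in
males.

Read depths are negative binomial with mean `meanDepth` (default 500, the
panel's reported average) and size `dispersion` (default 50 — mildly
overdispersed, near-Poisson); alternate reads are binomial at the true
dosage; absent amplicons receive at most `noiseFloor` (default 2) stray
reference-like reads; whole amplicons drop out with `dropoutProb` (default
0.02). Identical configurations (including the seed) give byte-identical
output files.

Three divergence scales matter, and their defaults encode the qualitative
structure the real system shows rather than estimates of any particular
locus (the per-species polymorphism levels of the real panel are unknown;
these are free parameters of the simulator):

- `divergence = 0.5`: moderate interspecific differentiation at nuclear and
  chloroplast loci.
- `xyDivergence = 0.8`: fraction of shared-SDR sites fixed between X and Y
  in every species. SDR dendrograms of these poplars split by sex before
  species (one female cluster, male clusters within). In the VAF model a
  female–female interspecific difference has amplitude 1 while a
  male–female X/Y difference has amplitude 0.5 (heterozygosity), so the sex
  split dominates only when
  $0.5\,\mathrm{xy} > 2\,d'(1 - \mathrm{xy})$ with $d'$ the realized
  per-pair divergence — i.e. `xyDivergence` above roughly 2/3 at these
  divergences. 0.8 encodes the observed sex-first structure.
- `yDivergence = 0.1`: between-species differentiation of the Y haplotype.
  The Y is a slowly diverging, effectively clonal lineage; keeping its
  interspecific divergence well below the autosomal scale preserves the
  sex-first SDR topology while leaving ample male-specific signal for
  paternal tracing.

What the generator does **not** emulate: read-level errors and FASTQ
artifacts, PCR chimeras, recombination within amplicons, copy-number
dynamics of the multicopy loci, within-species geographic structure,
backcrosses and multi-way hybrids, and ZW sex systems (*P. alba*). Passing
tests therefore demonstrate correctness of the inference chain under the
panel's statistical assumptions, not robustness to every artifact of real
amplicon data.

## Numerical and design choices

- Variant filters default to off: all records with AD are accepted
  (`minSiteDepth` and the coverage flags are the only gates), matching a
  pipeline that applies no QUAL/site filters before VAF computation.
- VCF coordinates are 1-based and preserved verbatim; the sample order of
  every output follows the sample sheet.
- Ward tie-breaks follow `stats::hclust`; merge heights are validated
  non-decreasing.
- Cluster labels are renumbered by first-appearing sample, so partitions are
  invariant to input permutation.
- The argmin tie tolerance (1e-9) and the distance-export precision
  (6 decimals) are determinism guards.
- Simulation studies in the test suite use 200 variants per locus group,
  depth 500, four samples per taxon (parentage; 20 replicates alternating
  reciprocal cross directions) and five-taxon strongly diverged panels
  (divergence 0.9, 50 replicates) for assignment; these sizes are the
  package's validation conditions.

## Known limitations

Mean-distance magnitudes reported for large real accession panels (for
example maternal means 0.7 vs 2.6) depend on that panel's variant counts and
missingness and are not reproducible from synthetic data; the decision rules
are therefore validated on such values as direct inputs, and recovery rates
are validated by simulation. Distances concatenated across locus groups are
unweighted by default; an optional per-group $1/\sqrt{\text{columns}}$
weight (`weightByGroup`) equalizes group contributions when variant counts
are very uneven. Consensus assignment presumes the reference
groups are correctly labeled; it does not detect novel taxa.
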