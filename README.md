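# amplitax

Taxon relationships, sex and hybrid parentage from amplicon-panel variant
allele frequencies, for poplars (*Populus*, sections *Aigeiros* and
*Tacamahaca*) and similar dioecious XY trees.

Cultivated poplars are very often interspecific hybrids that defeat both
morphological keys and discrete genotype calls. `amplitax` implements the
post-variant-calling inference chain for a targeted panel of 16 loci (NTS 5S
rDNA, ITS, nine single-copy nuclear loci, three chloroplast loci, the
sex-determining region SDR, and *ARR17*):

- **VAF matrices.** From multi-sample VCFs with allelic depths, the variant
  allele frequency per alternate allele is
  `VAF = alt / (ref + Σ alt)`. F1 hybrids sit at VAF ≈ 0.5 at sites where
  the parents are fixed for different alleles, which is what makes this
  coordinate system resolve hybrids.
- **Distances.** Pairwise-complete Euclidean distances with missing-data
  rescaling, `d(a,b) = sqrt((M/m_ab) Σ_shared (v_a − v_b)²)`, computed per
  named locus set (`traditional14`, `nuclear11`, `chloroplast3`, `sdr`,
  `arr17`, `all16`).
- **Clustering.** Ward's D2 on the distance matrix (squared-distance
  Lance–Williams recurrence, heights on the distance scale), with
  ultrametric Newick export. Bootstrap support is deliberately omitted:
  hybrids hop between parental clusters under subsampling, so the distance
  matrices are exported instead.
- **Sex genotyping.** The SDR portion carrying partial *ARR17* repeats is
  present only in males; coverage of the male-specific amplicons plus a
  sex-voted two-way cut of the SDR tree give per-sample calls.
- **Hybrid parentage.** Maternal species = argmin of mean chloroplast
  distance (chloroplast is maternally inherited); paternal species = argmin
  of mean SDR distance among male plants (sons carry the father's Y).
- **Consensus assignment.** An accession of uncertain affiliation gets a
  taxon label only when independent locus sets agree on the cluster it
  belongs to.
- **Synthetic panel simulator.** A seeded generator of species profiles, F1
  pedigrees with known cross direction, maternal chloroplast haplotypes, an
  XY SDR with male-specific amplicons, and negative-binomial read depths
  (~500 reads/amplicon), written as VCFv4.2 + TSV with a ground-truth
  table — so the whole chain is testable offline.

## Worked example

Simulate a small panel (three species, one F1 hybrid of known direction
sp01♀ × sp02♂, four samples each, depth 500) and run the full pipeline:

```r
library(amplitax)
cfg <- validateRunConfig(list(
  seed = 7, out_dir = "demo_out",
  simulate = list(
    n_species = 3, variants_per_amplicon = 20, divergence = 0.5,
    depth = list(mean_depth = 500, dropout_prob = 0),
    pedigrees = list(
      list(taxon = "P_nigra",      type = "species", mother = "sp01", father = "sp01", n = 4),
      list(taxon = "P_suaveolens", type = "species", mother = "sp02", father = "sp02", n = 4),
      list(taxon = "P_laurifolia", type = "species", mother = "sp03", father = "sp03", n = 4),
      list(taxon = "P_x_hybrid",   type = "F1", mother = "sp01", father = "sp02", n = 4))),
  locus_sets = c("traditional14", "chloroplast3", "sdr", "all16"),
  parentage = list(list(hybrid = "P_x_hybrid",
                        candidates = c("P_nigra", "P_suaveolens", "P_laurifolia"))),
  consensus = list(samples = list("P_x_hybrid_01"),
                   reference_taxa = c("P_nigra", "P_suaveolens", "P_laurifolia", "P_x_hybrid"))))
res <- runPipeline(cfg)
res$parentage$P_x_hybrid
```

The run logs each stage and prints:

```
ParentageResult for hybrid 'P_x_hybrid'
  maternal: P_nigra (margin 4.899)
    chloroplast mean distance to P_nigra: 0
    chloroplast mean distance to P_suaveolens: 5.568
    chloroplast mean distance to P_laurifolia: 4.899
  paternal: P_suaveolens (margin 1.433)
    male SDR mean distance to P_nigra: 2.53
    male SDR mean distance to P_suaveolens: 0.8169
    male SDR mean distance to P_laurifolia: 2.249
```

The hybrid's samples share the chloroplast haplotype of the simulated seed
parent (mean distance 0, margin 4.9 to the runner-up), and its sons sit
closest to the pollen parent's males on the SDR — the cross direction
sp01♀ × sp02♂ is recovered. Sex calls come with their evidence
(`ms_depth` = mean depth over male-specific amplicons; ~489 reads for a
male, ~1 stray read for a female):

```
   sample_id   call ms_depth presence_ratio cluster_vote
1 P_nigra_01   male  488.700    0.979266366         male
2 P_nigra_02 female    0.950    0.002141583       female
```

and the held-out sample is assigned by unanimity of three locus sets:

```
      sample_id candidate_all16 candidate_sdr candidate_traditional14  consensus
1 P_x_hybrid_01      P_x_hybrid    P_x_hybrid              P_x_hybrid P_x_hybrid
```

`demo_out/` then contains, per locus set, the VAF TSV (+ missing-mask), the
distance matrix TSV, the Newick tree and a cluster-assignment TSV, plus
`sex_calls.tsv`, `parentage.tsv(.txt)`, `consensus.tsv`, the simulated panel
under `sim/` and a run manifest. A thin command-line front end with
`simulate` and `run` subcommands is installed at
`inst/scripts/amplitax-cli.R`.

## Scope

The package starts from VCFs: read trimming, mapping and variant calling are
out of scope, as are figure styling, bootstrap dendrogram support and
quantitative admixture estimation for multi-way hybrids. See the methods
vignette (`vignettes/amplitax-methods.Rmd`) for the model, parameter
defaults and their rationale, and known limitations.
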