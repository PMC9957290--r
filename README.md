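# ibparch

Domain-architecture profiling of ice-binding proteins (and any other
target Pfam domain) in assembled metagenomes.

## The problem

Microbial ice-binding proteins (IBPs) are defined by the DUF3494 domain
(Pfam accession PF11999, normalized here to `pfam11999`). In polar
metagenomes these proteins occur in dozens of *domain architectures* —
ordered combinations of the DUF3494 domain with companion Pfam domains
(Ig-like folds, PEP C-terminal sorting motifs, adhesion repeats, further
DUF3494 copies) — and the architecture, together with signal-peptide (SP)
and transmembrane-domain (TMD) annotations, constrains what each protein
can be doing: secreted ice-recrystallisation inhibition, membrane-anchored
ice adhesion, or an intracellular role.

`ibparch` turns the per-gene annotation outputs of a standard metagenome
pipeline (gene calls, HMMER domain hits, Phobius-style topology calls, read
counts, taxonomy, MAG membership) into:

- an **architecture catalogue**: the ordered domain string of every
  target-domain protein, with copy counts, N/C-terminal companion splits
  anchored at the first target copy, SP/TMD localization classes and
  functional annotations of companion domains;
- **abundance vs prevalence accounting** per architecture. Abundance is the
  share of summed RPKM, `RPKM = reads / (length/10^3) / (total mapped
  reads/10^6)`; prevalence is the share of gene count. The two deliberately
  differ: one highly expressed gene can dominate abundance while barely
  registering in prevalence;
- **environment, taxon and localization breakdowns** of any architecture
  subset;
- **genomic context in MAGs**: nearest up/downstream genes (strand-aware,
  gap distances in bp), flanking-domain frequency tables, and tandem
  clusters of adjacent target genes;
- **community composition statistics**: Bray–Curtis dissimilarity
  `d(i,j) = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)` and one-way PERMANOVA
  (pseudo-F from within/between sums of squared dissimilarities, permutation
  p-value, R²);
- **tree utilities**: excision of target-domain subsequences for alignment,
  midpoint/outgroup rooting of externally inferred newick gene trees, and
  iTOL annotation-ring export;
- a **ground-truthed synthetic-data generator** that emits a complete
  dataset in every input format, so the whole pipeline can be validated
  end-to-end against planted truth.

## Worked example

```r
library(ibparch)

dir <- file.path(tempdir(), "demo")
sim <- simulate_dataset(sim_config(seed = 11), dir)
res <- run_all(run_config_for_dataset(dir, out_dir = file.path(tempdir(), "demo_out")))

head(res$abundance[, c("arch_string", "rpkm_total", "pct_abundance",
                       "n_genes", "pct_prevalence")], 5)
```

```
          arch_string rpkm_total pct_abundance n_genes pct_prevalence
1           pfam11999     388.05        53.744      42         60.870
2 pfam11999_pfam11999     215.51        29.849      12         17.391
3 pfam11999_pfam07589      64.36         8.914       3          4.348
4 pfam11999_pfam01391      24.74         3.427       4          5.797
5 pfam11999_pfam02010      11.28         1.563       1          1.449
```

Single-domain IBPs dominate both abundance (53.7% of summed RPKM) and
prevalence (60.9% of the 69 target genes recovered), followed by
double-domain IBPs — the catalogue is sorted by summed RPKM, and the two
percentage columns need not agree. The same result object carries the
environment breakdown of gene counts, the localization table, the MAG
context summary and the composition test:

```r
res$env_breakdown
#>      interior_ice sea_ice_interface        epipelagic meso_bathypelagic
#>             17.39             11.59             52.17             18.84
res$permanova
#> PERMANOVA (one-way): pseudo-F = 1.211 (df 3, 10), R2 = 0.267, p = 0.313 (999 permutations, seed 20200213)
res$context$summary$n_multi_target_mags
#> [1] 6
```

(Gene *counts* track the sampling design — here most samples are
epipelagic — while the per-environment *RPKM* shares track the planted
interior-ice read enrichment; see the vignette.)

All result tables are also written to `out_dir` as TSV with a provenance
header recording the package version and configuration hash. A thin CLI
wrapper for the `simulate` and `run-all` stages is installed at
`inst/scripts/ibparch.R`.

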