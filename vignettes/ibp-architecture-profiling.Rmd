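---
title: "Profiling ice-binding-protein domain architectures in metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ice-binding-protein domain architectures in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibparch)
```

## Scope and model

`ibparch` analyses proteins defined by a *target Pfam domain* — by default
DUF3494 (`pfam11999`), the domain that defines the dominant family of
microbial ice-binding proteins (IBPs) — in an assembled, annotated
metagenome. The package consumes the outputs of standard upstream tools
(gene calling, `hmmsearch` domain annotation, Phobius topology prediction,
read mapping, taxonomic classification, binning) and is deliberately
agnostic about how they were produced; it starts at the level of per-gene
records and ends at catalogue tables, composition statistics and
tree-annotation exports.

The unit of analysis is the **domain architecture**: the ordered list of
Pfam accessions along a protein, written lowercase and joined with
underscores (`pfam11999_pfam16130`). Signal peptides and transmembrane
domains are *not* part of the architecture string; they are overlay
classifiers (`none`, `sp_only`, `tmd_only`, `both`), because the
architecture notation in this field is Pfam-only and SP/TMD presence varies
within an architecture.

## Record-level filters

Two filters are applied before any accounting, mirroring common assembly
practice:

* **Contig length**: genes on contigs shorter than `min_contig_len`
  (default 500 bp, boundary-inclusive) are dropped. Short contigs carry
  unreliable gene models and inflate edge cases in neighbour analysis.
* **Eukaryote removal**: a gene is dropped when its own taxonomy record —
  or, failing that, its contig's record — is flagged eukaryotic. Whether
  such classifiers act on genes or whole contigs differs between upstream
  tools, so both keys are supported; when both exist the gene-level record
  wins (finer evidence). Genes with no record at all are retained and
  tallied as unclassified.

Both filters are idempotent and commute, which the test suite checks.

Domain hits are retained when their independent E-value is at most
`max_i_evalue` (default 1e-5). Curated model-specific gathering thresholds
are preferable when available, but they are not reproducible from a
domtblout file alone, so the package makes the threshold explicit,
configurable and logged.

## Architecture construction

Overlapping hits on one protein are resolved greedily by descending bit
score: a hit is discarded if its envelope overlaps an already-kept hit by
more than 50% of the shorter envelope (configurable), with deterministic
tie-breaks (lower envelope start, then lexicographic accession). Greedy
selection is not guaranteed to maximise total bit score; the tests compare
it against an exhaustive-subset oracle on small random cases and confirm
feasibility, score-boundedness and agreement in the large majority of
cases. The rule's virtue is determinism and independence of input order —
the architecture string is a pure function of the resolved hit set.

The N-/C-terminal split of companion domains is anchored at the **first**
target-domain copy: companions before it are N-terminal, everything else —
including companions interleaved between target copies, which do occur —
counts as C-terminal. A single consistent rule was preferred over
per-protein judgement calls.

Two published, non-identical definitions of a "structurally diverse" IBP
are both implemented and selected by `diverse_mode`: `"results"` (default)
calls a protein diverse when it has more than one domain of any kind;
`"methods"` additionally counts single-domain proteins carrying an SP
and/or TMD. Neither is presumed the intended one; analyses report which
definition they used.

Companion domains are annotated from a shipped, editable function map
(family name, broad functional grouping, Ig-like flag). Unknown accessions
are labelled `unmapped` and kept: dropping them would silently merge
distinct architectures.

## Abundance vs prevalence

Per-gene abundance is RPKM, `reads / (length/10^3) / (total mapped
reads/10^6)`, computed per sample and summed across samples without
between-sample renormalization (matching the summed-across-environments
accounting used for published abundance tables). The per-sample denominator
is the metadata column `total_mapped_reads`; upstream pipelines differ in
whether this means raw, filtered or assembled reads, so the value is
whatever the metadata provides, and the choice should be stated alongside
results. Samples created by pooling carry a flag; they are included by
default and can be excluded (`include_pooled = FALSE`).

Per architecture, the package reports both the share of grand-total RPKM
(**abundance**) and the share of gene count (**prevalence**). These are
deliberately distinct: a single high-coverage gene can dominate abundance
at negligible prevalence, and the test suite exercises exactly this
configuration. Percentages are computed at full precision and rendered to
2 decimals; ranking uses full precision with ties broken by architecture
string.

## Genomic context

Within MAGs, each target gene's nearest neighbour on either side is
recorded with the inter-gene *gap* in bp (exclusive of both genes; 0 for
abutting or overlapping genes — a 100–1000 gene followed at 1408–2000 is
407 bp from its neighbour). Upstream/downstream is oriented by the target
gene's strand, the biological convention for bacterial neighbourhoods; a
`strand_aware = FALSE` switch reproduces pure coordinate order for
sensitivity checks. First/last genes yield explicit contig-edge records.
Flanking frequencies are reported over non-edge slots and, since the
appropriate denominator is debatable, also over all slots (`pct_all`).
Neighbours without Pfam hits form a `"(no domain)"` class rather than
being dropped.

Tandem clusters are maximal runs of ≥ 2 target genes with at most
`max_intervening` non-target genes between consecutive members (default 0,
i.e. strictly adjacent; 1 admits the transposase-interrupted pairs seen in
real MAGs).

## Composition statistics

Bray–Curtis dissimilarity is computed on rows closed to proportions by
default, so it reflects composition rather than sequencing depth; closure
can be disabled. The one-way PERMANOVA uses the distance-based
sums-of-squares formulation (total SS as the sum of squared
dissimilarities over all pairs divided by *n*; within-group SS likewise per
group), pseudo-F with (a−1, n−a) degrees of freedom, and a permutation
p-value `(1 + #{F* ≥ F}) / (1 + n_permutations)` from whole-sample label
shuffles. The default 999 permutations and fixed default seed (20200213)
are always recorded in the result; any seed is accepted. For small designs
`permanova_exact()` enumerates every distinct label assignment and serves
as the reference implementation. The tests additionally cross-check
pseudo-F and R² against `vegan::adonis2` and verify the null rejection
rate by simulation.

## Tree tools

Target-domain envelopes are excised from protein sequences to build the
alignment input (`gene_id/start-end` per record; multi-copy proteins yield
multiple records). Alignment, trimming and tree inference are external by
design — the package contributes nothing there — and their newick output
is consumed for rooting: trees with fewer than `min_leaves_for_outgroup`
(default 60) leaves, multi-copy-architecture trees, or trees without
outgroup leaves are midpoint-rooted (delegated to `phangorn::midpoint`;
the root-adjacent depths then agree to numerical precision). Otherwise the
root is placed halfway along the edge subtending the smallest clade
containing the outgroup leaves present, with a warning when the outgroup
is not monophyletic and a midpoint fallback when it spans the whole tree.
Rooting preserves the leaf set, total branch length and the leaf-to-leaf
path-length matrix, which the tests verify to 1e-9.

iTOL annotation rings (environment, SP/TMD class, phylum, order,
architecture class, abundance bars) are exported as dataset files with
deterministic colour assignment; leaves with missing categorical values
render white, making gaps visible rather than silently coloured.

## The synthetic-data generator

`simulate_dataset()` writes a complete dataset — GFF3, domtblout, topology,
taxonomy, counts, sample metadata, MAG membership, contig lengths, protein
FASTA — together with per-gene ground truth, and is deterministic given its
seed. Its defaults encode the study conditions the package targets:

* **Sampling design**: 4 interior-ice, 3 sea-ice-interface, 6 epipelagic
  and 2 meso/bathypelagic samples (the 15-sample winter Arctic design,
  including two pooled epipelagic samples carried as a metadata flag).
* **Architecture spectrum**: ~70% single-domain, ~12% double-domain, with
  DUF4842, PEP-C-term, DUF11, triple-domain and repeat-bearing forms as
  minor classes — the gross prevalence shape reported for Arctic IBP
  catalogues.
* **SP/TMD rates** per architecture (e.g. 0.40 for single-domain, 0.58 for
  double-domain SP; 0.65 TMD for the PEP-C-term class), matching the
  published per-architecture percentages to two digits.
* **Read model**: negative-binomial counts (dispersion `nb_size = 5`, a
  typical metagenomic overdispersion scale) with mean proportional to gene
  length and, for target genes, a per-environment enrichment factor
  (defaults 10/4/0.5/0.1 from ice to depth). Because RPKM divides by
  length, the expected RPKM share of environment *e* has the closed form
  `n_samples[e]·enrichment[e] / Σ_j n_samples[j]·enrichment[j]`, which the
  recovery tests use.
* **Structure to trip over**: tandem target-gene runs (rate 0.15 per
  following slot), eukaryotic contigs, sub-500-bp contigs, unclassified
  genes (14%), and companion-domain-bearing neighbour genes.

What the generator does **not** emulate: sequence-level homology (proteins
are random strings with planted envelopes — they exercise excision, not
alignment), assembly artefacts, read-level error, and biologically
coherent per-organism taxonomy (target-gene taxonomy is drawn from
per-architecture pools, so a contig may host genes with different labels).
Passing the recovery tests therefore demonstrates that the *accounting* is
correct — architecture strings, splits, counts, shares, clusters, shares
of RPKM — not that upstream annotation errors are survivable.

`audit_dataset()` re-reads an emitted dataset and checks file-level
consistency (counts for every gene, a target hit for every planted target
gene, coordinates within contigs), so corrupted fixtures fail loudly.

## Problem sizes and numerical choices

The test suite runs at deliberately desk-scale sizes: 50-contig/500-gene
simulations for end-to-end recovery, exhaustive enumeration at n = 6 (20
assignments) and 500 null replicates at 99 permutations for PERMANOVA
calibration, and 100 random trees for rooting invariants. These sizes give
binomial/Monte-Carlo error bars tight enough for 3-standard-error checks
while keeping the default suite fast.

Degenerate inputs are contracts, not surprises: empty architecture
subsets warn and return empty tables; an absent target domain yields an
empty catalogue with a warning and a clean exit; all-zero composition rows
and single-group designs are errors naming the offending sample or the
degenerate design. Result tables are written in full precision with a
provenance header (package version, configuration hash) and round-trip to
6 significant figures.

## Limitations

The package quantifies *encoded* potential: RPKM of gene sequences, not
expression or activity. Architecture calls inherit any upstream
annotation errors (missed domains shorten architectures; chimeric genes
merge them). The PERMANOVA is one-way by design, matching the
single-factor environment comparisons it supports — nested or stratified
designs need a different tool. Outgroup sequences for rooting are
referenced by identifier only; a placeholder identifier list (marked
synthetic) stands in for the published outgroup accession set, which is
not bundled.
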