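Package: ibparch
Title: Domain-Architecture Profiling of Ice-Binding Proteins in Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for profiling Pfam domain architectures of target-domain
    proteins (by default DUF3494 / pfam11999 ice-binding proteins) in assembled
    metagenomes. Reads gene calls (GFF3), HMMER domtblout domain hits,
    Phobius-style topology tables, per-gene read counts, taxonomy and MAG
    membership tables; builds ordered domain-architecture catalogues with
    RPKM abundance and gene-count prevalence accounting, environment, taxon
    and localization breakdowns; profiles the genomic neighbourhood of target
    genes in metagenome-assembled genomes (nearest up/downstream genes, tandem
    gene clusters); computes Bray-Curtis dissimilarity and one-way PERMANOVA
    on community composition; prepares phylogenetic inputs (domain excision,
    midpoint/outgroup tree rooting) and exports iTOL annotation rings. A
    ground-truthed synthetic-data generator emits complete datasets in every
    input format for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    phangorn,
    phytools,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
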