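#' Default architecture spectrum for simulations
#'
#' Gene-count (prevalence) probabilities per planted architecture,
#' mirroring the gross proportions seen in Arctic sea-ice metagenomes:
#' roughly 70% single-domain and 12% double-domain ice-binding proteins,
#' with DUF4842-, PEP-C-term-, DUF11-bearing and triple-domain forms as
#' minor classes.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_architecture_spectrum <- function() {
  c("pfam11999" = 0.70,
    "pfam11999_pfam11999" = 0.12,
    "pfam11999_pfam16130" = 0.03,
    "pfam11999_pfam07589" = 0.03,
    "pfam11999_pfam11999_pfam11999" = 0.01,
    "pfam11999_pfam11999_pfam01345" = 0.01,
    "pfam11999_pfam02010" = 0.02,
    "pfam04519_pfam11999" = 0.02,
    "pfam13205_pfam13205_pfam11999" = 0.02,
    "pfam11999_pfam01391" = 0.02,
    "pfam11999_pfam07603" = 0.02)
}

default_taxonomy_pool <- function() {
  tibble::tibble(
    order = c("Flavobacteriales", "Alteromonadales", "Burkholderiales",
              "Oceanospirillales", "Cytophagales", "Micrococcales",
              "Cellvibrionales", "Verrucomicrobiales", "Rhodobacterales"),
    phylum = c("Bacteroidetes", "Gammaproteobacteria", "Betaproteobacteria",
               "Gammaproteobacteria", "Bacteroidetes", "Actinobacteria",
               "Gammaproteobacteria", "Verrucomicrobia",
               "Alphaproteobacteria"),
    weight = c(0.40, 0.25, 0.08, 0.07, 0.05, 0.05, 0.04, 0.03, 0.03))
}

#' Simulation configuration
#'
#' Defines the study conditions a simulated dataset emulates: the
#' per-environment sampling design (4 interior-ice, 3 sea-ice-interface,
#' 6 epipelagic, 2 meso/bathypelagic samples), the planted architecture
#' spectrum, per-architecture signal-peptide and TMD probabilities,
#' tandem-duplication rate, per-environment read enrichment of target
#' genes, taxonomy pools and negative-binomial count dispersion.
#'
#' @param seed Integer RNG seed.
#' @param samples_per_environment Named integer vector over the four
#'   environments.
#' @param n_contigs Number of regular contigs.
#' @param genes_per_contig Length-2 range (min, max) of genes per contig.
#' @param n_short_contigs Contigs shorter than 500 bp (exercise the
#'   assembly-length filter; their genes are excluded from ground truth).
#' @param p_target Probability a gene slot seeds a target-domain gene.
#' @param tandem_rate Probability that the slot following a target gene is
#'   forced to carry another target gene (same architecture), creating
#'   tandem clusters.
#' @param architecture_spectrum Named probabilities per architecture
#'   string; must sum to 1.
#' @param p_sp,p_tmd Named per-architecture probabilities of a signal
#'   peptide / of >= 1 transmembrane domain (unnamed scalar = all
#'   architectures).
#' @param enrichment Named multiplicative factor per environment on the
#'   expected read count of target genes.
#' @param taxonomy_pool Tibble `order`, `phylum`, `weight` used for gene
#'   taxonomy (target genes biased towards the first rows).
#' @param p_unclassified Probability a gene carries no taxonomy record.
#' @param p_eukaryote_contig Probability a contig is planted as eukaryotic
#'   (its genes carry no target domain and are removed by the pipeline).
#' @param base_depth Expected reads per kb for a non-target gene.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param total_mapped_reads Mapped-read total per sample.
#' @param p_neighbor_domain Probability a non-target gene carries 1-2
#'   companion Pfam hits (exercises neighbour-architecture profiling).
#' @return List of class `ibparch_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       samples_per_environment = c(interior_ice = 4L,
                                                   sea_ice_interface = 3L,
                                                   epipelagic = 6L,
                                                   meso_bathypelagic = 2L),
                       n_contigs = 50L,
                       genes_per_contig = c(10L, 10L),
                       n_short_contigs = 2L,
                       p_target = 0.12,
                       tandem_rate = 0.15,
                       architecture_spectrum =
                         default_architecture_spectrum(),
                       p_sp = c("pfam11999" = 0.40,
                                "pfam11999_pfam11999" = 0.58,
                                "pfam11999_pfam16130" = 0.37,
                                "pfam11999_pfam07589" = 0.53,
                                .default = 0.45),
                       p_tmd = c("pfam11999" = 0.09,
                                 "pfam11999_pfam07589" = 0.65,
                                 .default = 0.10),
                       enrichment = c(interior_ice = 10,
                                      sea_ice_interface = 4,
                                      epipelagic = 0.5,
                                      meso_bathypelagic = 0.1),
                       taxonomy_pool = default_taxonomy_pool(),
                       p_unclassified = 0.14,
                       p_eukaryote_contig = 0.04,
                       base_depth = 20,
                       nb_size = 5,
                       total_mapped_reads = 5e6,
                       p_neighbor_domain = 0.30) {
  cfg <- structure(as.list(environment()), class = "ibparch_sim_config")
  if (abs(sum(architecture_spectrum) - 1) > 1e-9) {
    abort("sim_config: architecture_spectrum must sum to 1")
  }
  probs <- c(p_target, tandem_rate, p_sp, p_tmd, p_unclassified,
             p_eukaryote_contig, p_neighbor_domain)
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: probabilities must lie in [0, 1]")
  }
  if (any(enrichment <= 0)) abort("sim_config: enrichment factors must be > 0")
  if (!setequal(names(samples_per_environment), ENVIRONMENTS)) {
    abort("sim_config: samples_per_environment must name all four environments")
  }
  cfg
}

prob_for <- function(p, arch) {
  if (!is.null(names(p)) && arch %in% names(p)) return(unname(p[arch]))
  if (".default" %in% names(p)) return(unname(p[".default"]))
  unname(p[1])
}

# Companion Pfams planted on non-target neighbour genes.
NEIGHBOR_POOL <- c("pfam07690", "pfam00072", "pfam04397", "pfam00578",
                   "pfam01131", "pfam01663", "pfam03050", "pfam00155",
                   "pfam14312", "pfam00132")

#' Expected per-environment share of target-gene RPKM
#'
#' Closed form for the simulation model: the expected RPKM of a target
#' gene is proportional to its environment's enrichment factor and does
#' not depend on gene length (length cancels between read mean and the
#' per-kb normalization), so the expected share of environment e is
#' `n_samples[e] * enrichment[e] / sum_j n_samples[j] * enrichment[j]`.
#'
#' @param config `ibparch_sim_config`.
#' @return Named numeric shares summing to 1.
#' @export
expected_env_rpkm_share <- function(config) {
  w <- config$samples_per_environment[ENVIRONMENTS] *
    config$enrichment[ENVIRONMENTS]
  setNames(as.numeric(w / sum(w)), ENVIRONMENTS)
}

#' Simulate a complete ground-truthed dataset
#'
#' Generates contigs carrying genes with planted domain architectures
#' (including multi-copy target genes and companion domains), planted
#' SP/TMD topology, tandem target-gene clusters, per-environment read
#' enrichment, order-level taxonomy and MAG membership, and writes every
#' file format the pipeline reads. Deterministic given `config$seed`.
#'
#' @param config `ibparch_sim_config` from [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list: `dir`, `files` (named paths) and `truth`
#'   (per-gene planted truth, planted spectrum, expected environment RPKM
#'   shares, tandem clusters and the config).
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "ibparch_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, simulate_dataset_impl(config, out_dir))
}

simulate_dataset_impl <- function(cfg, out_dir) {
  env_of_sample <- rep(names(cfg$samples_per_environment),
                       cfg$samples_per_environment)
  sample_ids <- sprintf("%s_s%02d", abbrev_env(env_of_sample),
                        sequence(cfg$samples_per_environment))
  samples <- tibble::tibble(sample_id = sample_ids,
                            environment = env_of_sample,
                            total_mapped_reads = cfg$total_mapped_reads,
                            pooled = FALSE)
  # mark one pooled epipelagic pair (pooling is metadata-only here)
  epi <- which(samples$environment == "epipelagic")
  if (length(epi) >= 2) samples$pooled[utils::tail(epi, 2)] <- TRUE

  spectrum <- cfg$architecture_spectrum
  arch_names <- names(spectrum)

  genes <- list(); hits <- list(); prot_seqs <- character()
  topo <- list(); taxa <- list()
  gene_n <- 0L
  contig_rows <- list()

  n_total_contigs <- cfg$n_contigs + cfg$n_short_contigs
  is_short <- c(rep(FALSE, cfg$n_contigs), rep(TRUE, cfg$n_short_contigs))
  for (ci in seq_len(n_total_contigs)) {
    contig_id <- sprintf("contig_%03d", ci)
    samp_i <- sample.int(nrow(samples), 1)
    samp <- samples$sample_id[samp_i]
    environment <- samples$environment[samp_i]
    is_euk <- !is_short[ci] && runif(1) < cfg$p_eukaryote_contig
    n_genes <- if (is_short[ci]) 1L else
      rint(cfg$genes_per_contig[1], cfg$genes_per_contig[2])

    # decide target slots with tandem forcing
    slot_target <- logical(n_genes)
    slot_arch <- character(n_genes)
    k <- 1L
    while (k <= n_genes) {
      if (!is_euk && !is_short[ci] && runif(1) < cfg$p_target) {
        arch <- sample(arch_names, 1, prob = spectrum)
        slot_target[k] <- TRUE; slot_arch[k] <- arch
        while (k < n_genes && runif(1) < cfg$tandem_rate) {
          k <- k + 1L
          slot_target[k] <- TRUE; slot_arch[k] <- arch
        }
      }
      k <- k + 1L
    }

    pos <- 1L
    for (gi in seq_len(n_genes)) {
      gene_n <- gene_n + 1L
      gene_id <- sprintf("gene_%05d", gene_n)
      if (slot_target[gi]) {
        doms <- strsplit(slot_arch[gi], "_", fixed = TRUE)[[1]]
        prot_len <- 60L + 230L * length(doms)
      } else if (is_short[ci]) {
        prot_len <- 50L
        doms <- character()
      } else {
        prot_len <- sample(100:500, 1)
        doms <- if (runif(1) < cfg$p_neighbor_domain) {
          sample(NEIGHBOR_POOL, sample(1:2, 1))
        } else character()
      }
      gene_len <- prot_len * 3L
      gap <- if (gi == 1) sample(10:120, 1) else sample(20:400, 1)
      start <- pos + gap
      end <- start + gene_len - 1L
      pos <- end
      strand <- sample(c("+", "-"), 1)
      genes[[gene_n]] <- tibble::tibble(
        gene_id = gene_id, contig_id = contig_id, sample_id = samp,
        environment = environment, start = start, end = end,
        strand = strand, is_target = slot_target[gi],
        arch_string = if (slot_target[gi]) slot_arch[gi] else
          paste(doms, collapse = "_"),
        prot_len = prot_len, is_euk_contig = is_euk,
        on_short_contig = is_short[ci])
      # domain hits: sequential envelopes along the protein
      if (length(doms) > 0) {
        env_start <- 30L + (seq_along(doms) - 1L) * 230L
        hits[[length(hits) + 1L]] <- tibble::tibble(
          protein_id = gene_id, pfam_acc = doms,
          env_start = pmin(env_start, prot_len - 10L),
          env_end = pmin(env_start + 199L, prot_len),
          bit_score = round(runif(length(doms), 50, 300), 1),
          i_evalue = 10^-runif(length(doms), 10, 50))
      }
      prot_seqs[gene_id] <- paste(
        sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], prot_len,
               replace = TRUE), collapse = "")
      if (slot_target[gi]) {
        arch <- slot_arch[gi]
        has_sp <- runif(1) < prob_for(cfg$p_sp, arch)
        n_tmd <- if (runif(1) < prob_for(cfg$p_tmd, arch))
          sample(1:2, 1, prob = c(0.9, 0.1)) else 0L
        topo[[length(topo) + 1L]] <- tibble::tibble(
          protein_id = gene_id, has_sp = has_sp, n_tmd = n_tmd)
        if (runif(1) >= cfg$p_unclassified) {
          row <- sample.int(nrow(cfg$taxonomy_pool), 1,
                            prob = cfg$taxonomy_pool$weight)
          taxa[[length(taxa) + 1L]] <- tibble::tibble(
            subject_id = gene_id, domain = "Bacteria",
            phylum = cfg$taxonomy_pool$phylum[row],
            order = cfg$taxonomy_pool$order[row], is_eukaryote = FALSE)
        }
      } else if (!is_euk && !is_short[ci] &&
                 runif(1) >= cfg$p_unclassified) {
        row <- sample.int(nrow(cfg$taxonomy_pool), 1,
                          prob = cfg$taxonomy_pool$weight)
        taxa[[length(taxa) + 1L]] <- tibble::tibble(
          subject_id = gene_id, domain = "Bacteria",
          phylum = cfg$taxonomy_pool$phylum[row],
          order = cfg$taxonomy_pool$order[row], is_eukaryote = FALSE)
      }
    }
    contig_len <- if (is_short[ci]) {
      sample(200:499, 1)  # short contigs violate the 500 bp filter
    } else pos + sample(10:200, 1)
    if (is_euk) {
      taxa[[length(taxa) + 1L]] <- tibble::tibble(
        subject_id = contig_id, domain = "Eukaryota",
        phylum = NA_character_, order = NA_character_,
        is_eukaryote = TRUE)
    }
    contig_rows[[ci]] <- tibble::tibble(
      contig_id = contig_id, length = as.integer(contig_len),
      sample_id = samp)
  }

  genes <- dplyr::bind_rows(genes)
  hits <- dplyr::bind_rows(hits)
  topo <- dplyr::bind_rows(topo)
  taxa <- dplyr::bind_rows(taxa)
  contigs <- dplyr::bind_rows(contig_rows)

  # short-contig gene coordinates must stay within the contig
  short_genes <- genes$on_short_contig
  if (any(short_genes)) {
    cl <- setNames(contigs$length, contigs$contig_id)
    genes$start[short_genes] <- 1L
    genes$end[short_genes] <-
      pmin(genes$start[short_genes] + 149L,
           as.integer(cl[genes$contig_id[short_genes]]))
  }

  # negative-binomial read counts in the gene's own sample
  enrich <- ifelse(genes$is_target,
                   cfg$enrichment[genes$environment], 1)
  mu <- cfg$base_depth * (genes$end - genes$start + 1) / 1000 * enrich
  counts <- tibble::tibble(
    gene_id = genes$gene_id, sample_id = genes$sample_id,
    read_count = rnbinom(nrow(genes), size = cfg$nb_size, mu = mu))

  # MAGs: group ~half of each sample's regular contigs into bins of 2-5
  mags <- list()
  for (s in samples$sample_id) {
    cands <- contigs$contig_id[contigs$sample_id == s &
                                 !contigs$contig_id %in%
                                 genes$contig_id[genes$is_euk_contig] &
                                 contigs$length >= 500]
    cands <- sample(cands, floor(length(cands) * 0.6))
    mi <- 0L
    while (length(cands) >= 2) {
      mi <- mi + 1L
      take <- min(length(cands), sample(2:5, 1))
      mags[[length(mags) + 1L]] <- tibble::tibble(
        mag_id = sprintf("%s_mag%02d", s, mi),
        contig_id = cands[seq_len(take)],
        completeness = round(runif(1, 60, 99), 1),
        contamination = round(runif(1, 0, 8), 1))
      cands <- cands[-seq_len(take)]
    }
  }
  mags <- dplyr::bind_rows(mags)

  files <- write_dataset_files(out_dir, genes, hits, topo, taxa, counts,
                               samples, mags, contigs, prot_seqs)

  eligible <- !genes$is_euk_contig & !genes$on_short_contig
  truth_genes <- genes[, c("gene_id", "contig_id", "sample_id",
                           "environment", "start", "end", "strand",
                           "is_target", "arch_string", "is_euk_contig",
                           "on_short_contig")]
  truth_genes$has_sp <- topo$has_sp[match(truth_genes$gene_id,
                                          topo$protein_id)]
  truth_genes$n_tmd <- topo$n_tmd[match(truth_genes$gene_id,
                                        topo$protein_id)]
  tx <- taxa[taxa$subject_id %in% genes$gene_id, ]
  truth_genes$order <- tx$order[match(truth_genes$gene_id, tx$subject_id)]
  truth_genes$phylum <- tx$phylum[match(truth_genes$gene_id,
                                        tx$subject_id)]

  clusters <- dplyr::bind_rows(lapply(
    split(genes[eligible, ], genes$contig_id[eligible]),
    function(gc) find_tandem_clusters(
      gc[order(gc$start), ],
      gc$gene_id[gc$is_target], max_intervening = 0)))

  truth <- list(genes = truth_genes,
                spectrum = cfg$architecture_spectrum,
                expected_env_rpkm_share = expected_env_rpkm_share(cfg),
                tandem_clusters = clusters,
                config = cfg)
  write_result_table(truth_genes, file.path(out_dir, "truth_genes.tsv"),
                     cfg)
  invisible(list(dir = out_dir, files = files, truth = truth))
}

# uniform integer in [lo, hi], safe when lo == hi
rint <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  sample(seq.int(lo, hi), 1)

abbrev_env <- function(env) {
  c(interior_ice = "II", sea_ice_interface = "SII", epipelagic = "Epi",
    meso_bathypelagic = "BaMe")[env]
}

write_dataset_files <- function(out_dir, genes, hits, topo, taxa, counts,
                                samples, mags, contigs, prot_seqs) {
  p <- function(f) file.path(out_dir, f)
  # GFF3
  gff <- p("genes.gff")
  con <- file(gff, "wt")
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tibparch_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;sample_id=%s",
                     genes$contig_id, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$sample_id), con)
  close(con)
  # domtblout (hmmsearch orientation: target = protein, query = model)
  dom <- p("hits.domtblout")
  con <- file(dom, "wt")
  writeLines("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target", con)
  if (nrow(hits) > 0) {
    plen <- genes$prot_len[match(hits$protein_id, genes$gene_id)]
    acc_fmt <- toupper(sub("pfam", "PF", hits$pfam_acc))
    writeLines(sprintf(
      "%s - %d %s %s.12 200 %.1e %.1f 0.1 1 1 %.1e %.1e %.1f 0.1 1 200 %d %d %d %d 0.95 -",
      hits$protein_id, plen, sub("pfam", "DOM", hits$pfam_acc), acc_fmt,
      hits$i_evalue, hits$bit_score + 5, hits$i_evalue / 10,
      hits$i_evalue, hits$bit_score, hits$env_start + 2L,
      hits$env_end - 2L, hits$env_start, hits$env_end), con)
  }
  close(con)
  # plain TSVs
  wt <- function(df, f) {
    write.table(as.data.frame(df), p(f), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    p(f)
  }
  wt(topo, "topology.tsv")
  wt(taxa, "taxonomy.tsv")
  wt(counts, "counts.tsv")
  wt(samples, "samples.tsv")
  wt(mags, "mags.tsv")
  wt(contigs, "contigs.tsv")
  # protein FASTA
  faa <- p("proteins.faa")
  aa <- Biostrings::AAStringSet(prot_seqs)
  Biostrings::writeXStringSet(aa, faa, width = 70)
  list(gff = gff, domtblout = dom, topology = p("topology.tsv"),
       taxonomy = p("taxonomy.tsv"), counts = p("counts.tsv"),
       samples = p("samples.tsv"), mags = p("mags.tsv"),
       contigs = p("contigs.tsv"), proteins = faa,
       truth_genes = p("truth_genes.tsv"))
}

#' Audit a simulated dataset against its ground truth
#'
#' File-level consistency checks: every gene in the GFF has a read count;
#' every planted target gene has at least one target-domain hit in the
#' domtblout; all coordinates are valid and within their contig; every
#' sample referenced has metadata.
#'
#' @param dataset_dir Directory written by [simulate_dataset()].
#' @param truth Truth list from [simulate_dataset()].
#' @return List with `pass` (logical) and `issues` (character).
#' @export
audit_dataset <- function(dataset_dir, truth) {
  issues <- character()
  note <- function(msg) issues <<- c(issues, msg)
  genes <- read_gff(file.path(dataset_dir, "genes.gff"))
  counts <- read_counts(file.path(dataset_dir, "counts.tsv"))
  hits <- read_domtblout(file.path(dataset_dir, "hits.domtblout"),
                         max_i_evalue = Inf)
  contigs <- read_result_table(file.path(dataset_dir, "contigs.tsv"))
  samples <- read_sample_meta(file.path(dataset_dir, "samples.tsv"))

  no_counts <- setdiff(genes$gene_id, counts$gene_id)
  if (length(no_counts) > 0) {
    note(paste0("genes without read counts: ",
                paste(head(no_counts, 5), collapse = ", ")))
  }
  target <- default_target_pfam()
  planted <- truth$genes$gene_id[truth$genes$is_target]
  with_hit <- unique(hits$protein_id[hits$pfam_acc == target])
  orphans <- setdiff(planted, with_hit)
  if (length(orphans) > 0) {
    note(paste0("planted target genes without a ", target, " hit: ",
                paste(head(orphans, 5), collapse = ", ")))
  }
  if (any(genes$end < genes$start)) note("gene with end < start")
  cl <- setNames(contigs$length, contigs$contig_id)
  over <- genes$end > cl[genes$contig_id]
  if (any(is.na(over))) note("gene on contig with no recorded length")
  else if (any(over)) {
    note(paste0("gene extends beyond contig end: ",
                paste(head(genes$gene_id[over], 5), collapse = ", ")))
  }
  bad_samp <- setdiff(unique(genes$sample_id), samples$sample_id)
  if (length(bad_samp) > 0) {
    note(paste0("samples without metadata: ",
                paste(bad_samp, collapse = ", ")))
  }
  list(pass = length(issues) == 0, issues = issues)
}
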