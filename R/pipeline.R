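#' Pipeline run configuration
#'
#' Bundles input paths, thresholds and mode flags for [run_all()].
#'
#' @param gff,domtblout,topology,taxonomy,counts,samples,mags,contigs,proteins
#'   Input file paths (`mags`, `contigs`, `proteins`, `topology`,
#'   `taxonomy` optional, `NULL` to skip the dependent stages).
#' @param out_dir Output directory for result tables.
#' @param target_pfam Target domain accession (any accepted spelling;
#'   normalized).
#' @param max_i_evalue Domain-hit i-Evalue threshold (default 1e-5).
#' @param min_contig_len Contig length filter in bp (default 500).
#' @param max_overlap Envelope overlap tolerance (default 0.5).
#' @param diverse_mode `"results"` or `"methods"` (see
#'   [classify_diverse()]).
#' @param strand_aware Orient neighbours by target-gene strand.
#' @param include_pooled Include pooled samples in abundance accounting.
#' @param max_intervening Tandem-cluster gap tolerance (default 0).
#' @param rank Taxonomic rank for composition/PERMANOVA (default
#'   `"order"`).
#' @param n_permutations,seed PERMANOVA permutations and seed.
#' @return List of class `ibparch_run_config`.
#' @export
run_config <- function(gff, domtblout, counts, samples,
                       topology = NULL, taxonomy = NULL, mags = NULL,
                       contigs = NULL, proteins = NULL,
                       out_dir = tempfile("ibparch_out_"),
                       target_pfam = default_target_pfam(),
                       max_i_evalue = 1e-5, min_contig_len = 500,
                       max_overlap = 0.5, diverse_mode = "results",
                       strand_aware = TRUE, include_pooled = TRUE,
                       max_intervening = 0, rank = "order",
                       n_permutations = 999, seed = 20200213) {
  cfg <- structure(as.list(environment()), class = "ibparch_run_config")
  paths <- c(gff = gff, domtblout = domtblout, counts = counts,
             samples = samples, topology = topology, taxonomy = taxonomy,
             mags = mags, contigs = contigs, proteins = proteins)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    abort(paste0("run_config: input file(s) not found: ",
                 paste(sprintf("%s (%s)", missing, names(missing)),
                       collapse = ", ")))
  }
  cfg$target_pfam <- normalize_pfam_acc(target_pfam)
  cfg
}

#' Build a run configuration for a simulated dataset directory
#' @param dir Directory written by [simulate_dataset()].
#' @param ... Overrides passed to [run_config()].
#' @return `ibparch_run_config`.
#' @export
run_config_for_dataset <- function(dir, ...) {
  p <- function(f) file.path(dir, f)
  run_config(gff = p("genes.gff"), domtblout = p("hits.domtblout"),
             counts = p("counts.tsv"), samples = p("samples.tsv"),
             topology = p("topology.tsv"), taxonomy = p("taxonomy.tsv"),
             mags = p("mags.tsv"), contigs = p("contigs.tsv"),
             proteins = p("proteins.faa"), ...)
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return `ibparch_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input reading and record-level filters (contig
#' length, eukaryote removal), architecture construction, RPKM abundance
#' aggregation, MAG genomic-context profiling, community composition
#' statistics (Bray-Curtis + PERMANOVA) and tree-input preparation
#' (target-domain excision). All result tables are written to
#' `config$out_dir` with a config-hash provenance header; outputs are pure
#' functions of the inputs and configuration.
#'
#' @param config `ibparch_run_config`.
#' @return Invisible list with elements `genes`, `architectures`,
#'   `abundance`, `env_breakdown`, `localization`, `taxon`, `context`,
#'   `permanova`, `files`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "ibparch_run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write_result_table(df, path, cfg)
    files <<- c(files, path)
  }

  genes <- run_stage("filter", {
    g <- read_gff(cfg$gff)
    if (!is.null(cfg$contigs)) {
      ct <- read_result_table(cfg$contigs)
      g <- filter_contigs(g, ct, cfg$min_contig_len)
    }
    if (!is.null(cfg$taxonomy)) {
      tax <- read_taxonomy(cfg$taxonomy)
      g <- drop_eukaryotes(g, tax)
    }
    g
  })

  hits <- run_stage("hits", read_domtblout(cfg$domtblout,
                                           cfg$max_i_evalue))
  hits <- hits[hits$protein_id %in% genes$gene_id, ]
  topo <- if (is.null(cfg$topology)) NULL else
    run_stage("topology", read_topology(cfg$topology))

  arch <- run_stage("architectures", {
    a <- build_architectures(hits, topo, cfg$target_pfam,
                             cfg$max_overlap, cfg$diverse_mode)
    if (nrow(a) == 0) {
      warn(paste0("run_all: no gene carries ", cfg$target_pfam,
                  "; catalogue is empty"))
    }
    a$sample_id <- genes$sample_id[match(a$gene_id, genes$gene_id)]
    if (!is.null(cfg$taxonomy)) {
      tax <- read_taxonomy(cfg$taxonomy)
      gl <- tax[match(a$gene_id, tax$subject_id), ]
      a$order <- if ("order" %in% names(gl)) gl$order else NA_character_
      a$phylum <- if ("phylum" %in% names(gl)) gl$phylum else
        NA_character_
    }
    annotate_function(a)
  })

  samples <- run_stage("samples", read_sample_meta(cfg$samples))
  arch$environment <- samples$environment[match(arch$sample_id,
                                                samples$sample_id)]

  abundance <- run_stage("abundance", {
    counts <- read_counts(cfg$counts)
    rk <- gene_rpkm(genes, counts, samples, cfg$include_pooled)
    aggregate_architectures(arch, rk)
  })
  env_breakdown <- if (nrow(arch) > 0) {
    counts_by_env <- table(factor(arch$environment,
                                  levels = ENVIRONMENTS))
    environment_breakdown(setNames(as.integer(counts_by_env),
                                   names(counts_by_env)))
  } else NULL
  localization <- localization_breakdown(arch)
  taxon <- if (!is.null(cfg$taxonomy) && nrow(arch) > 0)
    taxon_breakdown(arch, cfg$rank) else NULL

  context <- if (!is.null(cfg$mags) && nrow(arch) > 0) {
    run_stage("context", {
      mags <- read_mag_members(cfg$mags)
      arch_map <- neighbor_arch_map(hits, cfg$max_overlap)
      nbr <- scan_neighbors_mags(genes, mags, arch$gene_id, arch_map,
                                 cfg$strand_aware)
      list(neighbors = nbr,
           frequencies = if (nrow(nbr) > 0) flanking_frequencies(nbr)
                         else NULL,
           summary = mag_context_summary(genes, mags, arch$gene_id,
                                         cfg$max_intervening))
    })
  } else NULL

  perm <- if (!is.null(cfg$taxonomy) && nrow(arch) > 1) {
    run_stage("stats", {
      g2 <- arch[!is.na(arch$order) & !is.na(arch$sample_id), ]
      ok <- tryCatch({
        m <- composition_matrix(g2, rank = cfg$rank)
        grouping <- samples$environment[match(rownames(m),
                                              samples$sample_id)]
        if (length(unique(grouping)) < 2 || nrow(m) < 3) NULL else
          permanova(bray_curtis(m), grouping, cfg$n_permutations,
                    cfg$seed)
      }, error = function(e) {
        warn(paste0("run_all: PERMANOVA skipped: ", conditionMessage(e)))
        NULL
      })
      ok
    })
  } else NULL

  tree_input <- if (!is.null(cfg$proteins) && nrow(arch) > 0) {
    run_stage("tree-prep", {
      seqs <- Biostrings::readAAStringSet(cfg$proteins)
      names(seqs) <- sub("\\s.*$", "", names(seqs))
      kept <- dplyr::bind_rows(lapply(
        split(hits[hits$protein_id %in% arch$gene_id, ],
              hits$protein_id[hits$protein_id %in% arch$gene_id]),
        resolve_overlaps, max_overlap = cfg$max_overlap))
      dom <- excise_domains(seqs, kept, cfg$target_pfam)
      path <- file.path(cfg$out_dir, "target_domains.faa")
      Biostrings::writeXStringSet(dom, path, width = 70)
      files <- c(files, path)
      dom
    })
  } else NULL

  emit(arch[, setdiff(names(arch), "domain_order")],
       "architectures.tsv")
  flat_ab <- abundance[, c("arch_string", "rpkm_total", "pct_abundance",
                           "n_genes", "pct_prevalence")]
  emit(flat_ab, "abundance.tsv")
  if (!is.null(env_breakdown)) {
    emit(tibble::tibble(environment = names(env_breakdown),
                        pct = as.numeric(env_breakdown)),
         "environment_breakdown.tsv")
  }
  emit(localization$classes, "localization_classes.tsv")
  if (!is.null(taxon)) emit(taxon$taxa, "taxon_breakdown.tsv")
  if (!is.null(context)) {
    emit(context$neighbors, "neighbors.tsv")
    if (!is.null(context$frequencies)) {
      emit(context$frequencies$architecture,
           "flanking_architectures.tsv")
      emit(context$frequencies$domain, "flanking_domains.tsv")
    }
    cl <- context$summary$clusters
    if (nrow(cl) > 0) {
      flat <- cl
      flat$member_gene_ids <- vapply(cl$member_gene_ids, paste,
                                     character(1), collapse = ",")
      flat$intervening_gene_counts <-
        vapply(cl$intervening_gene_counts, paste, character(1),
               collapse = ",")
      emit(flat, "tandem_clusters.tsv")
    }
  }
  if (!is.null(perm)) {
    jsonlite::write_json(unclass(perm),
                         file.path(cfg$out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(cfg$out_dir, "permanova.json"))
  }

  invisible(list(genes = genes, architectures = arch,
                 abundance = abundance, env_breakdown = env_breakdown,
                 localization = localization, taxon = taxon,
                 context = context, permanova = perm,
                 tree_input = tree_input, files = files))
}

# Architecture strings over ALL resolved Pfam hits of each gene (used for
# neighbour profiling, where non-target genes matter too).
neighbor_arch_map <- function(hits, max_overlap = 0.5) {
  if (nrow(hits) == 0) return(character())
  by_prot <- split(hits, hits$protein_id)
  vapply(by_prot, function(h) {
    kept <- resolve_overlaps(h, max_overlap)
    paste(tolower(kept$pfam_acc), collapse = "_")
  }, character(1))
}
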