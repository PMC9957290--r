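#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `rpkm = read_count / (gene_length_bp/1000) / (total_mapped_reads/1e6)`.
#' Vectorized over all arguments.
#'
#' @param read_count Non-negative read counts.
#' @param gene_length_bp Gene lengths in bp (>= 1).
#' @param total_mapped_reads Per-sample mapped-read totals (>= 1).
#' @return Numeric RPKM values.
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp < 1)) {
    abort("rpkm: gene_length_bp must be >= 1")
  }
  if (any(total_mapped_reads < 1)) {
    abort("rpkm: total_mapped_reads must be >= 1")
  }
  if (any(read_count < 0)) abort("rpkm: negative read_count")
  read_count / (gene_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Per-gene RPKM summed across samples
#'
#' Joins counts with gene lengths and per-sample totals and sums RPKM over
#' samples per gene; there is no between-sample renormalization, matching
#' the summed-across-environments accounting used for abundance tables.
#'
#' @param genes Gene table.
#' @param counts Read-count table (`gene_id`, `sample_id`, `read_count`).
#' @param sample_meta Sample metadata with `total_mapped_reads`.
#' @param include_pooled Include samples flagged as pooled (default TRUE).
#' @return Tibble `gene_id`, `rpkm` (one row per gene in `genes`; genes
#'   with no counts get 0).
#' @export
gene_rpkm <- function(genes, counts, sample_meta, include_pooled = TRUE) {
  if (!include_pooled) {
    sample_meta <- sample_meta[!sample_meta$pooled, ]
    counts <- counts[counts$sample_id %in% sample_meta$sample_id, ]
  }
  lens <- gene_lengths(genes)
  unknown <- setdiff(unique(counts$gene_id), names(lens))
  counts <- counts[!counts$gene_id %in% unknown, ]
  totals <- setNames(sample_meta$total_mapped_reads, sample_meta$sample_id)
  missing <- setdiff(unique(counts$sample_id), names(totals))
  if (length(missing) > 0) {
    abort(paste0("gene_rpkm: no metadata for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  counts$rpkm <- rpkm(counts$read_count, lens[counts$gene_id],
                      totals[counts$sample_id])
  agg <- dplyr::summarise(dplyr::group_by(counts, .data$gene_id),
                          rpkm = sum(.data$rpkm), .groups = "drop")
  out <- tibble::tibble(gene_id = genes$gene_id)
  out$rpkm <- agg$rpkm[match(out$gene_id, agg$gene_id)]
  out$rpkm[is.na(out$rpkm)] <- 0
  out
}

#' Aggregate genes into per-architecture abundance records
#'
#' Groups target-domain genes by architecture string and computes summed
#' RPKM, percent of grand-total RPKM (abundance), gene counts and percent
#' of all target genes (prevalence), plus environment, order-level taxonomy
#' and localization breakdowns. Abundance and prevalence are deliberately
#' distinct statistics: a single highly abundant gene can dominate RPKM
#' while contributing one gene to prevalence.
#'
#' @param architectures Architecture tibble (needs `gene_id`,
#'   `arch_string`, `localization_class`; optional `environment`, `order`).
#' @param rpkm_by_gene Tibble `gene_id`, `rpkm` covering every gene.
#' @return Tibble sorted by `rpkm_total` descending (ties by
#'   `arch_string`), with list columns `env_counts`, `env_pcts`,
#'   `order_counts`, `loc_counts`.
#' @export
aggregate_architectures <- function(architectures, rpkm_by_gene) {
  missing <- setdiff(architectures$gene_id, rpkm_by_gene$gene_id)
  if (length(missing) > 0) {
    abort(paste0("aggregate_architectures: no RPKM for gene(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  if (nrow(architectures) == 0) {
    return(tibble::tibble(arch_string = character(),
                          rpkm_total = numeric(),
                          pct_abundance = numeric(), n_genes = integer(),
                          pct_prevalence = numeric(), env_counts = list(),
                          order_counts = list(), loc_counts = list(),
                          env_pcts = list()))
  }
  a <- architectures
  a$rpkm <- rpkm_by_gene$rpkm[match(a$gene_id, rpkm_by_gene$gene_id)]
  grand_rpkm <- sum(a$rpkm)
  n_total <- nrow(a)
  count_map <- function(x) {
    x[is.na(x)] <- "unclassified"
    tab <- table(x)
    setNames(as.integer(tab), names(tab))
  }
  grp <- split(a, a$arch_string)
  out <- dplyr::bind_rows(lapply(grp, function(g) {
    tibble::tibble(
      arch_string = g$arch_string[1],
      rpkm_total = sum(g$rpkm),
      pct_abundance = if (grand_rpkm > 0) 100 * sum(g$rpkm) / grand_rpkm
                      else 0,
      n_genes = nrow(g),
      pct_prevalence = 100 * nrow(g) / n_total,
      env_counts = list(if ("environment" %in% names(g))
        count_map(g$environment) else integer()),
      order_counts = list(if ("order" %in% names(g))
        count_map(g$order) else integer()),
      loc_counts = list(count_map(g$localization_class))
    )
  }))
  out$env_pcts <- lapply(out$env_counts, function(cc) {
    if (length(cc) == 0) numeric() else round(pct(cc), 2)
  })
  out[order(-out$rpkm_total, out$arch_string), ]
}

#' Percent breakdown of gene counts by environment
#'
#' @param counts_by_environment Named non-negative counts, at least one
#'   positive.
#' @param digits Decimal places for rendering (default 2); percentages are
#'   computed at full precision and rounded only for display.
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' environment_breakdown(c(interior_ice = 3581, sea_ice_interface = 797,
#'                         epipelagic = 60, meso_bathypelagic = 8))
environment_breakdown <- function(counts_by_environment, digits = 2) {
  if (any(counts_by_environment < 0)) {
    abort("environment_breakdown: negative counts")
  }
  if (sum(counts_by_environment) == 0) {
    abort("environment_breakdown: all counts are zero")
  }
  round(pct(counts_by_environment), digits)
}

#' Signal-peptide / transmembrane-domain localization breakdown
#'
#' Percentages of the four localization classes over a subset of
#' architectures, the TMD-count spectrum (0, 1, 2, 3, 4+), and the percent
#' of proteins with both an SP and >= 1 TMD and with neither.
#'
#' @param architectures Architecture tibble.
#' @param subset Optional logical vector, character vector of
#'   `arch_string`s, or predicate function selecting rows.
#' @return List with elements `n`, `classes` (tibble of class/percent),
#'   `tmd_spectrum` (tibble), `pct_sp` (any SP), `pct_tmd` (any TMD),
#'   `pct_both` and `pct_neither`.
#' @export
localization_breakdown <- function(architectures, subset = NULL) {
  a <- architectures
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(a)
            else if (is.character(subset)) a$arch_string %in% subset
            else subset
    a <- a[keep, ]
  }
  if (nrow(a) == 0) {
    warn("localization_breakdown: empty subset")
    return(list(n = 0L,
                classes = tibble::tibble(class = character(),
                                         n = integer(), pct = numeric()),
                tmd_spectrum = tibble::tibble(n_tmd = character(),
                                              n = integer(),
                                              pct = numeric()),
                pct_sp = NA_real_, pct_tmd = NA_real_,
                pct_both = NA_real_, pct_neither = NA_real_))
  }
  n_prot <- nrow(a)
  cls <- factor(a$localization_class, levels = LOCALIZATION_CLASSES)
  cls_tab <- table(cls)
  cls_pct <- round(pct(as.numeric(cls_tab), n_prot), 2)
  tmd_band <- cut(a$n_tmd, c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
                  labels = c("0", "1", "2", "3", "4+"))
  tmd_tab <- table(tmd_band)
  tmd_pct <- round(pct(as.numeric(tmd_tab), n_prot), 2)
  n <- n_prot
  list(
    n = n,
    classes = tibble::tibble(class = names(cls_tab),
                             n = as.integer(cls_tab),
                             pct = cls_pct),
    tmd_spectrum = tibble::tibble(n_tmd = names(tmd_tab),
                                  n = as.integer(tmd_tab),
                                  pct = tmd_pct),
    pct_sp = round(100 * sum(a$has_sp) / n, 2),
    pct_tmd = round(100 * sum(a$n_tmd >= 1) / n, 2),
    pct_both = round(100 * sum(a$has_sp & a$n_tmd >= 1) / n, 2),
    pct_neither = round(100 * sum(!a$has_sp & a$n_tmd == 0) / n, 2)
  )
}

#' Taxonomic breakdown of a gene subset at a chosen rank
#'
#' @param architectures Architecture tibble carrying taxonomy columns
#'   (e.g. `order`, `phylum`); `NA` labels count as unclassified.
#' @param rank One of `"phylum"`, `"order"`, `"genus"`.
#' @return List with `n`, `n_classified`, `pct_classified`, and `taxa`
#'   (tibble of taxon, count and percent over the whole subset, sorted by
#'   count descending); unclassified genes are tallied separately, never as
#'   a taxon.
#' @export
taxon_breakdown <- function(architectures, rank = "order") {
  if (!rank %in% c("phylum", "order", "genus")) {
    abort("taxon_breakdown: rank must be phylum, order or genus")
  }
  if (!rank %in% names(architectures)) {
    abort(paste0("taxon_breakdown: architectures table has no '", rank,
                 "' column"))
  }
  labels <- architectures[[rank]]
  n <- length(labels)
  classified <- !is.na(labels) & labels != ""
  tab <- sort(table(labels[classified]), decreasing = TRUE)
  list(
    n = n,
    n_classified = sum(classified),
    pct_classified = if (n > 0) round(100 * sum(classified) / n, 2)
                     else NA_real_,
    taxa = tibble::tibble(taxon = names(tab), n = as.integer(tab),
                          pct = round(pct(as.numeric(tab), n), 2))
  )
}
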