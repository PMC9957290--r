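#' Nearest flanking genes of target genes on one contig
#'
#' For each target gene, records its nearest neighbour on either side.
#' Upstream/downstream is oriented by the *target* gene's strand by default
#' (for a minus-strand gene the upstream neighbour lies at higher
#' coordinates); `strand_aware = FALSE` reproduces pure coordinate order.
#' Distances are the inter-gene gap in bp, exclusive of both genes
#' (`next.start - this.end - 1` for coordinate-adjacent genes), floored at
#' 0 for overlapping genes. First/last genes on a contig yield edge records
#' with `at_contig_edge = TRUE` and no neighbour fields.
#'
#' @param genes_on_contig Gene table for a single contig, sorted by
#'   `start`.
#' @param target_gene_ids Ids of the target genes.
#' @param arch_by_gene Optional named character vector mapping any gene id
#'   to its domain-architecture string (over all its Pfam hits); genes
#'   absent from the map get `""` (the no-domain class).
#' @param mag_id MAG identifier carried into the records.
#' @param strand_aware Orient by target-gene strand (default TRUE).
#' @return Tibble of neighbour records, two rows (upstream, downstream) per
#'   target gene.
#' @export
scan_neighbors <- function(genes_on_contig, target_gene_ids,
                           arch_by_gene = NULL, mag_id = NA_character_,
                           strand_aware = TRUE) {
  g <- genes_on_contig
  if (length(unique(g$contig_id)) > 1) {
    abort("scan_neighbors: genes must come from a single contig")
  }
  if (is.unsorted(g$start)) {
    abort("scan_neighbors: genes must be sorted by start")
  }
  arch_of <- function(id) {
    if (is.null(arch_by_gene)) return("")
    v <- arch_by_gene[id]
    if (is.na(v)) "" else unname(v)
  }
  rows <- list()
  for (i in which(g$gene_id %in% target_gene_ids)) {
    for (side in c("lower", "higher")) {
      j <- if (side == "lower") i - 1L else i + 1L
      # strand flip: for a minus-strand target, lower coords = downstream
      direction <- if (!strand_aware || g$strand[i] == "+") {
        if (side == "lower") "upstream" else "downstream"
      } else {
        if (side == "lower") "downstream" else "upstream"
      }
      if (j < 1L || j > nrow(g)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mag_id = mag_id, contig_id = g$contig_id[i],
          ibp_gene_id = g$gene_id[i], direction = direction,
          neighbor_gene_id = NA_character_, distance_bp = NA_integer_,
          neighbor_arch = NA_character_, at_contig_edge = TRUE)
      } else {
        gap <- if (side == "lower") g$start[i] - g$end[j] - 1L
               else g$start[j] - g$end[i] - 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mag_id = mag_id, contig_id = g$contig_id[i],
          ibp_gene_id = g$gene_id[i], direction = direction,
          neighbor_gene_id = g$gene_id[j],
          distance_bp = max(gap, 0L),
          neighbor_arch = arch_of(g$gene_id[j]), at_contig_edge = FALSE)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Neighbour scan across all MAG contigs
#'
#' @param genes Gene table (any number of contigs).
#' @param mag_members MAG membership table (`mag_id`, `contig_id`); only
#'   contigs in MAGs are scanned.
#' @param target_gene_ids Target gene ids.
#' @param arch_by_gene,strand_aware Passed to [scan_neighbors()].
#' @return Combined neighbour-record tibble.
#' @export
scan_neighbors_mags <- function(genes, mag_members, target_gene_ids,
                                arch_by_gene = NULL, strand_aware = TRUE) {
  mag_of <- setNames(mag_members$mag_id, mag_members$contig_id)
  g <- genes[genes$contig_id %in% names(mag_of), ]
  g <- g[order(g$contig_id, g$start), ]
  out <- lapply(split(g, g$contig_id), function(gc) {
    if (!any(gc$gene_id %in% target_gene_ids)) return(NULL)
    scan_neighbors(gc, target_gene_ids, arch_by_gene,
                   mag_id = unname(mag_of[gc$contig_id[1]]),
                   strand_aware = strand_aware)
  })
  dplyr::bind_rows(out)
}

#' Frequencies of flanking architectures and domains
#'
#' Ranks what lies next to target genes, separately upstream and
#' downstream, both by whole neighbour architecture and by individual
#' domain (a neighbour with k domains contributes k entries to the domain
#' table and one to the architecture table). Percentages are reported over
#' non-edge records (`pct`) and over all neighbour slots including contig
#' edges (`pct_all`), since either denominator may be wanted.
#'
#' @param neighbor_records Tibble from [scan_neighbors()].
#' @return List with elements `architecture` and `domain`, each a tibble
#'   with columns `direction`, `value`, `n`, `pct`, `pct_all`. Neighbours
#'   without Pfam hits appear as the `"(no domain)"` class.
#' @export
flanking_frequencies <- function(neighbor_records) {
  nr <- neighbor_records
  non_edge <- nr[!nr$at_contig_edge, ]
  if (nrow(non_edge) == 0) {
    warn("flanking_frequencies: all neighbour slots are contig edges")
    empty <- tibble::tibble(direction = character(), value = character(),
                            n = integer(), pct = numeric(),
                            pct_all = numeric())
    return(list(architecture = empty, domain = empty))
  }
  one_dir <- function(dir) {
    slots_all <- sum(nr$direction == dir)
    x <- non_edge[non_edge$direction == dir, ]
    if (nrow(x) == 0) return(NULL)
    arch_lab <- ifelse(is.na(x$neighbor_arch) | x$neighbor_arch == "",
                       "(no domain)", x$neighbor_arch)
    at <- sort(table(arch_lab), decreasing = TRUE)
    arch_tab <- tibble::tibble(direction = dir, value = names(at),
                               n = as.integer(at),
                               pct = round(pct(as.numeric(at), nrow(x)), 2),
                               pct_all = round(pct(as.numeric(at),
                                                   slots_all), 2))
    doms <- unlist(strsplit(arch_lab[arch_lab != "(no domain)"], "_",
                            fixed = TRUE))
    dom_tab <- if (length(doms) == 0) NULL else {
      dt <- sort(table(doms), decreasing = TRUE)
      tibble::tibble(direction = dir, value = names(dt),
                     n = as.integer(dt),
                     pct = round(pct(as.numeric(dt), length(doms)), 2),
                     pct_all = round(pct(as.numeric(dt), length(doms)), 2))
    }
    list(arch = arch_tab, dom = dom_tab)
  }
  parts <- lapply(c("upstream", "downstream"), one_dir)
  list(
    architecture = dplyr::bind_rows(lapply(parts, `[[`, "arch")),
    domain = dplyr::bind_rows(lapply(parts, `[[`, "dom"))
  )
}

#' Find tandem clusters of target genes on a contig
#'
#' A tandem cluster is a maximal run of >= 2 target genes with at most
#' `max_intervening` non-target genes between consecutive members.
#'
#' @param genes_on_contig Gene table for one contig, sorted by `start`.
#' @param target_gene_ids Target gene ids.
#' @param max_intervening Maximum non-target genes tolerated between
#'   consecutive cluster members (default 0 = strictly adjacent).
#' @return Tibble with one row per cluster: `contig_id`, `n_members`,
#'   list columns `member_gene_ids` and `intervening_gene_counts` (per gap).
#' @export
find_tandem_clusters <- function(genes_on_contig, target_gene_ids,
                                 max_intervening = 0) {
  g <- genes_on_contig
  if (is.unsorted(g$start)) {
    abort("find_tandem_clusters: genes must be sorted by start")
  }
  pos <- which(g$gene_id %in% target_gene_ids)
  if (length(pos) < 2) {
    return(tibble::tibble(contig_id = character(), n_members = integer(),
                          member_gene_ids = list(),
                          intervening_gene_counts = list()))
  }
  gaps <- diff(pos) - 1L
  brk <- c(0L, cumsum(gaps > max_intervening))
  runs <- split(seq_along(pos), brk)
  rows <- lapply(runs, function(ii) {
    if (length(ii) < 2) return(NULL)
    tibble::tibble(
      contig_id = g$contig_id[1], n_members = length(ii),
      member_gene_ids = list(g$gene_id[pos[ii]]),
      intervening_gene_counts = list(as.integer(gaps[ii[-length(ii)]])))
  })
  dplyr::bind_rows(rows)
}

#' Per-MAG target-gene summary
#'
#' @param genes Gene table.
#' @param mag_members MAG membership table.
#' @param target_gene_ids Target gene ids.
#' @param max_intervening Passed to [find_tandem_clusters()].
#' @return List with `per_mag` (tibble `mag_id`, `n_target_genes`,
#'   `n_clusters`), `n_mags_with_target`, `n_multi_target_mags`,
#'   `max_per_mag` and `clusters` (tibble over all contigs with `mag_id`).
#' @export
mag_context_summary <- function(genes, mag_members, target_gene_ids,
                                max_intervening = 0) {
  mag_of <- setNames(mag_members$mag_id, mag_members$contig_id)
  g <- genes[genes$contig_id %in% names(mag_of), ]
  g <- g[order(g$contig_id, g$start), ]
  g$mag_id <- unname(mag_of[g$contig_id])
  tg <- g[g$gene_id %in% target_gene_ids, ]
  per_mag_counts <- table(tg$mag_id)
  clus <- dplyr::bind_rows(lapply(split(g, g$contig_id), function(gc) {
    cl <- find_tandem_clusters(gc, target_gene_ids, max_intervening)
    if (nrow(cl) > 0) cl$mag_id <- unname(mag_of[gc$contig_id[1]])
    cl
  }))
  per_mag <- tibble::tibble(
    mag_id = names(per_mag_counts),
    n_target_genes = as.integer(per_mag_counts))
  per_mag$n_clusters <- if (nrow(clus) > 0) {
    cc <- table(clus$mag_id)
    as.integer(dplyr::coalesce(as.integer(cc[per_mag$mag_id]), 0L))
  } else 0L
  list(per_mag = per_mag,
       n_mags_with_target = nrow(per_mag),
       n_multi_target_mags = sum(per_mag$n_target_genes > 1),
       max_per_mag = if (nrow(per_mag) > 0) max(per_mag$n_target_genes)
                     else 0L,
       clusters = clus)
}
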