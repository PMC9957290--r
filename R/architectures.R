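#' Resolve overlapping domain hits on one protein
#'
#' Greedy selection by descending bit score: a hit is discarded when its
#' envelope overlaps an already-kept hit by more than `max_overlap` of the
#' shorter envelope. Ties in score are broken deterministically by lower
#' `env_start`, then lexicographic `pfam_acc`.
#'
#' @param hits Domain-hit tibble for a single protein.
#' @param max_overlap Maximum tolerated overlap fraction of the shorter
#'   envelope (default 0.5).
#' @return The retained hits, sorted by `env_start`.
#' @export
resolve_overlaps <- function(hits, max_overlap = 0.5) {
  if (nrow(hits) <= 1) return(hits[order(hits$env_start), ])
  if (length(unique(hits$protein_id)) > 1) {
    abort("resolve_overlaps: hits must all be on one protein")
  }
  ord <- order(-hits$bit_score, hits$env_start, hits$pfam_acc)
  h <- hits[ord, ]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(h$env_end[i], h$env_end[j]) -
        max(h$env_start[i], h$env_start[j]) + 1L
      shorter <- min(h$env_end[i] - h$env_start[i],
                     h$env_end[j] - h$env_start[j]) + 1L
      if (ov > max_overlap * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- h[keep, ]
  out[order(out$env_start, out$pfam_acc), ]
}

localization_class <- function(has_sp, n_tmd) {
  dplyr::case_when(
    has_sp & n_tmd >= 1 ~ "both",
    has_sp ~ "sp_only",
    n_tmd >= 1 ~ "tmd_only",
    TRUE ~ "none"
  )
}

#' Build the domain architecture of one protein
#'
#' Orders the (overlap-resolved) hits by envelope start and derives the
#' architecture string plus all architecture-level classifiers. The split
#' into N- and C-terminal companion domains is anchored at the *first* copy
#' of the target domain; companion domains interleaved between target
#' copies count as C-terminal.
#'
#' @param hits Overlap-resolved hits for one protein (see
#'   [resolve_overlaps()]); must contain at least one target-domain hit.
#' @param topology Optional one-row topology record (`has_sp`, `n_tmd`) for
#'   the protein; when absent, `has_sp = FALSE`, `n_tmd = 0`.
#' @param target Target domain accession (default `"pfam11999"`, DUF3494).
#' @return One-row tibble with columns `gene_id`, `arch_string`,
#'   `n_domains`, `n_target`, `n_nterm`, `n_cterm`, `has_sp`, `n_tmd`,
#'   `localization_class`, and a list column `domain_order`.
#' @export
build_architecture <- function(hits, topology = NULL,
                               target = default_target_pfam()) {
  if (nrow(hits) == 0 || !any(hits$pfam_acc == target)) {
    abort(paste0("build_architecture: no ", target, " hit on protein; ",
                 "callers must pre-filter to target-domain proteins"))
  }
  h <- hits[order(hits$env_start, hits$pfam_acc), ]
  order_vec <- tolower(h$pfam_acc)
  first_target <- match(target, order_vec)
  is_target <- order_vec == target
  has_sp <- FALSE; n_tmd <- 0L
  if (!is.null(topology) && nrow(topology) > 0) {
    has_sp <- isTRUE(as.logical(topology$has_sp[1]))
    n_tmd <- as.integer(topology$n_tmd[1])
  }
  tibble::tibble(
    gene_id = h$protein_id[1],
    arch_string = paste(order_vec, collapse = "_"),
    n_domains = length(order_vec),
    n_target = sum(is_target),
    n_nterm = sum(!is_target[seq_len(first_target - 1)]),
    n_cterm = sum(!is_target) - sum(!is_target[seq_len(first_target - 1)]),
    has_sp = has_sp,
    n_tmd = n_tmd,
    localization_class = localization_class(has_sp, n_tmd),
    domain_order = list(order_vec)
  )
}

#' Build the architecture catalogue for all target-domain proteins
#'
#' Convenience wrapper applying [resolve_overlaps()] and
#' [build_architecture()] to every protein with at least one retained
#' target-domain hit, and attaching topology and diversity classification.
#'
#' @param hits Domain-hit tibble over any number of proteins.
#' @param topology Optional topology table (`protein_id`, `has_sp`,
#'   `n_tmd`). Proteins without a record default to no SP / no TMD.
#' @param target Target domain accession.
#' @param max_overlap Passed to [resolve_overlaps()].
#' @param diverse_mode Passed to [classify_diverse()].
#' @return Architecture tibble, one row per target-domain protein, with an
#'   `is_diverse` column.
#' @export
build_architectures <- function(hits, topology = NULL,
                                target = default_target_pfam(),
                                max_overlap = 0.5,
                                diverse_mode = "results") {
  target_prot <- unique(hits$protein_id[hits$pfam_acc == target])
  if (length(target_prot) == 0) {
    warn(paste0("build_architectures: no protein carries ", target))
    out <- build_architecture(
      tibble::tibble(protein_id = "x", pfam_acc = target, env_start = 1L,
                     env_end = 2L, bit_score = 0, i_evalue = 0),
      target = target)[0, ]
    out$is_diverse <- logical()
    return(out)
  }
  topo_by_id <- NULL
  if (!is.null(topology) && nrow(topology) > 0) {
    topo_by_id <- split(topology, topology$protein_id)
  }
  rows <- lapply(target_prot, function(p) {
    kept <- resolve_overlaps(hits[hits$protein_id == p, ], max_overlap)
    if (!any(kept$pfam_acc == target)) return(NULL)
    build_architecture(kept, topo_by_id[[p]], target)
  })
  out <- dplyr::bind_rows(rows)
  n_missing <- if (is.null(topo_by_id)) nrow(out) else
    sum(!out$gene_id %in% names(topo_by_id))
  if (n_missing > 0) {
    inform(sprintf(
      "build_architectures: %d protein(s) without topology record; assuming no SP/TMD",
      n_missing))
  }
  out$is_diverse <- classify_diverse(out, mode = diverse_mode)
  out[order(out$gene_id), ]
}

#' Classify architectures as structurally diverse
#'
#' Two non-identical published definitions are supported and neither is
#' presumed canonical: `"results"` calls a protein diverse when it carries
#' more than one domain (target or companion); `"methods"` additionally
#' counts single-domain proteins bearing a signal peptide and/or
#' transmembrane domain(s).
#'
#' @param arch Architecture tibble (needs `n_domains`, `has_sp`, `n_tmd`).
#' @param mode `"results"` (default) or `"methods"`.
#' @return Logical vector.
#' @export
classify_diverse <- function(arch, mode = c("results", "methods")) {
  if (!is.character(mode) || !all(mode %in% c("results", "methods"))) {
    abort("classify_diverse: mode must be \"results\" or \"methods\"")
  }
  mode <- match.arg(mode)
  multi <- arch$n_domains > 1
  if (mode == "results") multi
  else multi | arch$has_sp | arch$n_tmd >= 1
}

#' Load the shipped Pfam function map
#'
#' Maps companion-domain accessions to family names, broad functional
#' groupings and an Ig-like flag; shipped as an editable TSV.
#'
#' @param path Optional path to an alternative map.
#' @return A tibble with columns `pfam_acc`, `family_name`,
#'   `broad_function`, `ig_like`.
#' @export
default_function_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "function_map.tsv", package = "ibparch")
  }
  df <- read_tsv_checked(path, c("pfam_acc", "family_name", "broad_function",
                                 "ig_like"), "function map")
  df$ig_like <- as.logical(df$ig_like)
  df
}

#' Annotate architectures with domain functions
#'
#' Labels every domain of each architecture with its family name, broad
#' functional grouping and Ig-like status. Accessions missing from the map
#' are labelled `"unmapped"` rather than dropped, so distinct architectures
#' are never silently merged.
#'
#' @param arch Architecture tibble with a `domain_order` list column.
#' @param function_map Function map tibble (default: shipped map).
#' @return `arch` with added columns `family_names`, `broad_functions`
#'   (semicolon-collapsed over non-target domains, in architecture order)
#'   and `has_ig_like`.
#' @export
annotate_function <- function(arch, function_map = default_function_map()) {
  fam <- setNames(function_map$family_name, function_map$pfam_acc)
  fun <- setNames(function_map$broad_function, function_map$pfam_acc)
  ig <- setNames(function_map$ig_like, function_map$pfam_acc)
  target <- default_target_pfam()
  ann <- lapply(arch$domain_order, function(doms) {
    companions <- doms[doms != target]
    list(
      fam = paste(dplyr::coalesce(fam[companions], "unmapped"),
                  collapse = ";"),
      fun = paste(dplyr::coalesce(fun[companions], "unmapped"),
                  collapse = ";"),
      ig = any(dplyr::coalesce(ig[companions], FALSE))
    )
  })
  arch$family_names <- vapply(ann, `[[`, character(1), "fam")
  arch$broad_functions <- vapply(ann, `[[`, character(1), "fun")
  arch$has_ig_like <- vapply(ann, `[[`, logical(1), "ig")
  arch
}
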