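#' Excise target-domain subsequences from proteins
#'
#' Cuts every retained target-domain envelope out of its protein, yielding
#' the per-domain sequences that alignment and tree inference consume.
#' Multi-copy proteins yield one record per copy.
#'
#' @param protein_sequences `Biostrings::AAStringSet` (or named character
#'   vector) keyed by gene id.
#' @param hits Overlap-resolved domain hits; only rows matching `target`
#'   are excised.
#' @param target Target domain accession.
#' @return `AAStringSet` with ids `gene_id/env_start-env_end`.
#' @export
excise_domains <- function(protein_sequences, hits,
                           target = default_target_pfam()) {
  if (!methods::is(protein_sequences, "AAStringSet")) {
    protein_sequences <- Biostrings::AAStringSet(protein_sequences)
  }
  h <- hits[hits$pfam_acc == target, ]
  missing <- setdiff(unique(h$protein_id), names(protein_sequences))
  if (length(missing) > 0) {
    abort(paste0("excise_domains: no sequence for protein(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  lens <- Biostrings::width(protein_sequences)[
    match(h$protein_id, names(protein_sequences))]
  beyond <- h$env_end > lens | h$env_start < 1
  if (any(beyond)) {
    abort(paste0("excise_domains: envelope beyond sequence end for: ",
                 paste(head(h$protein_id[beyond], 10), collapse = ", ")))
  }
  out <- Biostrings::subseq(protein_sequences[h$protein_id],
                            start = h$env_start, end = h$env_end)
  names(out) <- sprintf("%s/%d-%d", h$protein_id, h$env_start, h$env_end)
  out
}

#' Root a gene tree by midpoint or outgroup
#'
#' Trees with fewer than `min_leaves_for_outgroup` leaves, with
#' `multi_copy = TRUE`, or with an empty outgroup set are midpoint-rooted
#' (root halfway along the longest leaf-to-leaf path). Otherwise the tree
#' is rooted on the edge subtending the smallest clade containing all
#' outgroup leaves present in the tree; a warning is issued when those
#' leaves are not monophyletic. Branch-length sum and the leaf-to-leaf
#' path-length matrix are preserved.
#'
#' @param tree `ape::phylo` tree with branch lengths.
#' @param outgroup_leaf_ids Character vector of outgroup tip labels
#'   (may be empty).
#' @param min_leaves_for_outgroup Below this leaf count midpoint rooting is
#'   used (default 60).
#' @param multi_copy Force midpoint rooting (used for trees of multi-copy
#'   target-domain architectures).
#' @return Rooted `phylo`; the rooting method is attached as attribute
#'   `rooting`.
#' @export
root_tree <- function(tree, outgroup_leaf_ids = character(),
                      min_leaves_for_outgroup = 60, multi_copy = FALSE) {
  if (is.null(tree$edge.length)) {
    abort("root_tree: tree must have branch lengths")
  }
  n_leaves <- length(tree$tip.label)
  use_midpoint <- multi_copy || n_leaves < min_leaves_for_outgroup ||
    length(outgroup_leaf_ids) == 0
  if (use_midpoint) {
    out <- phangorn::midpoint(tree)
    attr(out, "rooting") <- "midpoint"
    return(out)
  }
  present <- intersect(outgroup_leaf_ids, tree$tip.label)
  if (length(present) == 0) {
    abort(paste0("root_tree: outgroup rooting requested but no outgroup ",
                 "leaf is in the tree; missing: ",
                 paste(head(outgroup_leaf_ids, 10), collapse = ", ")))
  }
  ut <- ape::unroot(tree)
  if (length(present) == 1) {
    node <- match(present, ut$tip.label)
  } else {
    node <- ape::getMRCA(ut, present)
    clade_tips <- ape::extract.clade(ut, node)$tip.label
    if (!setequal(clade_tips, present)) {
      warn(paste0("root_tree: outgroup is not monophyletic; rooting on ",
                  "the smallest clade spanning it (", length(clade_tips),
                  " leaves)"))
    }
    root_node <- ape::Ntip(ut) + 1L
    if (node == root_node) {
      warn("root_tree: outgroup spans the whole tree; falling back to midpoint")
      out <- phangorn::midpoint(tree)
      attr(out, "rooting") <- "midpoint"
      return(out)
    }
  }
  edge_len <- ut$edge.length[which(ut$edge[, 2] == node)]
  out <- phytools::reroot(ut, node, position = edge_len / 2)
  attr(out, "rooting") <- "outgroup"
  out
}

#' Decide and apply the rooting rule for a set of gene trees
#'
#' @param trees `ape::multiPhylo` or list of `phylo` objects.
#' @param outgroup_leaf_ids Outgroup tip labels shared across trees.
#' @param min_leaves_for_outgroup Leaf-count threshold (default 60).
#' @param multi_copy Logical vector (recycled) marking multi-copy trees.
#' @return List of rooted trees.
#' @export
root_trees <- function(trees, outgroup_leaf_ids = character(),
                       min_leaves_for_outgroup = 60, multi_copy = FALSE) {
  multi_copy <- rep_len(multi_copy, length(trees))
  lapply(seq_along(trees), function(i) {
    root_tree(trees[[i]], outgroup_leaf_ids, min_leaves_for_outgroup,
              multi_copy[i])
  })
}

# Deterministic categorical palette; recycled colours keep exports stable
# across runs regardless of category order in the input.
ITOL_PALETTE <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                  "#e6ab02", "#a6761d", "#666666", "#1f78b4", "#b2df8a",
                  "#fb9a99", "#cab2d6")

ENV_COLORS <- c(interior_ice = "#000000", sea_ice_interface = "#555555",
                epipelagic = "#bbbbbb", meso_bathypelagic = "#ffffff")

itol_color_for <- function(values, color_map = NULL) {
  vals <- sort(unique(values[!is.na(values)]))
  pal <- setNames(rep_len(ITOL_PALETTE, length(vals)), vals)
  if (!is.null(color_map)) pal[names(color_map)] <- color_map
  out <- pal[values]
  out[is.na(values)] <- "#ffffff"  # unknown categories render white
  unname(out)
}

#' Export iTOL annotation rings for a rooted tree
#'
#' Writes one iTOL dataset file per annotation ring: colour strips for the
#' categorical rings (environment, localization, phylum, order,
#' architecture class) and a simple bar chart for abundance. Colour
#' assignment is deterministic (sorted category order over a fixed
#' palette); leaves with missing categorical values are rendered white.
#'
#' @param tree Rooted `phylo`.
#' @param annotations Tibble with `leaf_id` plus any of `environment`,
#'   `localization_class`, `phylum`, `order`, `arch_class`,
#'   `abundance_rpkm`.
#' @param dir Output directory.
#' @param color_map Optional named colour overrides (category -> hex).
#' @return Invisible character vector of files written.
#' @export
export_itol_rings <- function(tree, annotations, dir,
                              color_map = NULL) {
  if (anyDuplicated(annotations$leaf_id)) {
    abort(paste0("export_itol_rings: duplicate leaf id(s): ",
                 paste(unique(annotations$leaf_id[
                   duplicated(annotations$leaf_id)]), collapse = ", ")))
  }
  extra <- setdiff(annotations$leaf_id, tree$tip.label)
  if (length(extra) > 0) {
    abort(paste0("export_itol_rings: annotation leaf id(s) not in tree: ",
                 paste(head(extra, 10), collapse = ", ")))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annotations[match(tree$tip.label, annotations$leaf_id), ]
  ann$leaf_id <- tree$tip.label  # leaves without a record become "unknown"
  files <- character()
  strip <- function(column, label, colors = NULL) {
    if (!column %in% names(ann)) return(NULL)
    path <- file.path(dir, paste0("itol_", column, ".txt"))
    vals <- as.character(ann[[column]])
    cols <- itol_color_for(vals, colors)
    con <- file(path, "wt"); on.exit(close(con), add = TRUE)
    writeLines(c("DATASET_COLORSTRIP", "SEPARATOR TAB",
                 paste0("DATASET_LABEL\t", label),
                 "COLOR\t#888888", "DATA"), con)
    writeLines(paste(ann$leaf_id, cols, sep = "\t"), con)
    files <<- c(files, path)
    path
  }
  strip("environment", "Environment", ENV_COLORS)
  strip("localization_class", "SP/TMD", color_map)
  strip("phylum", "Phylum", color_map)
  strip("order", "Order", color_map)
  strip("arch_class", "Domain architecture", color_map)
  if ("abundance_rpkm" %in% names(ann)) {
    path <- file.path(dir, "itol_abundance.txt")
    vals <- ann$abundance_rpkm
    vals[is.na(vals)] <- 0
    con <- file(path, "wt")
    writeLines(c("DATASET_SIMPLEBAR", "SEPARATOR TAB",
                 "DATASET_LABEL\tAbundance (RPKM)", "COLOR\t#1b9e77",
                 "DATA"), con)
    writeLines(paste(ann$leaf_id, format(vals, trim = TRUE,
                                         scientific = FALSE),
                     sep = "\t"), con)
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}

#' Classify an architecture string into the annotation-ring vocabulary
#'
#' @param arch_string Character vector of architecture strings.
#' @param target Target domain accession.
#' @return Factor-like character vector over `{single, double, triple,
#'   duf4842, pep_cterm, other}`.
#' @export
arch_class <- function(arch_string, target = default_target_pfam()) {
  n_target <- vapply(strsplit(arch_string, "_", fixed = TRUE),
                     function(d) sum(d == target), integer(1))
  n_dom <- lengths(strsplit(arch_string, "_", fixed = TRUE))
  dplyr::case_when(
    arch_string == paste0(target, "_pfam16130") ~ "duf4842",
    arch_string == paste0(target, "_pfam07589") ~ "pep_cterm",
    n_target == 1 & n_dom == 1 ~ "single",
    n_target == 2 & n_dom == 2 ~ "double",
    n_target == 3 & n_dom == 3 ~ "triple",
    TRUE ~ "other"
  )
}
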