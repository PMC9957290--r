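#' Read gene calls from a GFF3 file
#'
#' Parses CDS/gene features into a gene table. Coordinates are kept 1-based
#' inclusive as in the file; records are returned sorted by
#' `(contig_id, start)`. The sample a gene belongs to is taken from a
#' `sample_id` attribute when present, otherwise from the `sample_id`
#' argument.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types (column 3) to keep.
#' @param sample_id Fallback sample id applied to features lacking a
#'   `sample_id` attribute.
#' @return A tibble with columns `gene_id`, `contig_id`, `sample_id`,
#'   `start`, `end`, `strand`.
#' @export
read_gff <- function(path, feature_types = c("CDS", "gene"),
                     sample_id = NA_character_) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(gene_id = character(), contig_id = character(),
                          sample_id = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    abort(paste0("Malformed GFF3 line ", bad, " in ", path,
                 ": expected 9 tab-separated fields, got ",
                 nf[which(nf != 9L)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type_ok <- m[, 3] %in% feature_types
  m <- m[type_ok, , drop = FALSE]
  idx <- idx[type_ok]
  if (nrow(m) == 0) {
    return(tibble::tibble(gene_id = character(), contig_id = character(),
                          sample_id = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    abort(paste0("Malformed GFF3 line ", bad, ": non-numeric coordinates"))
  }
  if (any(end < start)) {
    bad <- idx[which(end < start)[1]]
    abort(paste0("Malformed GFF3 line ", bad,
                 ": end < start (zero/negative-length feature)"))
  }
  if (any(!m[, 7] %in% c("+", "-"))) {
    bad <- idx[which(!m[, 7] %in% c("+", "-"))[1]]
    abort(paste0("Malformed GFF3 line ", bad, ": strand must be + or -"))
  }
  gene_id <- attr_value(m[, 9], "ID")
  if (anyNA(gene_id)) {
    bad <- idx[which(is.na(gene_id))[1]]
    abort(paste0("GFF3 line ", bad, ": feature lacks an ID attribute"))
  }
  if (anyDuplicated(gene_id)) {
    abort(paste0("Duplicate gene ID(s) in ", path, ": ",
                 paste(head(unique(gene_id[duplicated(gene_id)]), 5),
                       collapse = ", ")))
  }
  samp <- attr_value(m[, 9], "sample_id")
  samp[is.na(samp)] <- sample_id
  out <- tibble::tibble(gene_id = gene_id, contig_id = m[, 1],
                        sample_id = samp, start = start, end = end,
                        strand = m[, 7])
  dplyr::arrange(out, .data$contig_id, .data$start)
}

attr_value <- function(attr_col, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  m <- regmatches(attr_col, regexpr(pat, attr_col, perl = TRUE))
  out <- rep(NA_character_, length(attr_col))
  hit <- grepl(pat, attr_col, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses domain hits, normalizes Pfam accessions (e.g. `"PF11999.6"` to
#' `"pfam11999"`) and drops hits whose independent E-value exceeds
#' `max_i_evalue`. The number of dropped hits is reported via a message.
#'
#' @param path Path to a HMMER3 `--domtblout` file.
#' @param max_i_evalue Maximum independent E-value to retain (default 1e-5;
#'   HMMER model-specific gathering cutoffs are not reproducible offline, so
#'   the threshold is explicit and configurable).
#' @return A tibble with columns `protein_id`, `pfam_acc`, `env_start`,
#'   `env_end`, `bit_score`, `i_evalue`.
#' @export
read_domtblout <- function(path, max_i_evalue = 1e-5) {
  if (!file.exists(path)) abort(paste0("domtblout file not found: ", path))
  lines <- readLines(path)
  idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(idx) == 0) {
    return(tibble::tibble(protein_id = character(), pfam_acc = character(),
                          env_start = integer(), env_end = integer(),
                          bit_score = double(), i_evalue = double()))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L)) {
    bad <- idx[which(nf < 23L)[1]]
    abort(paste0("Malformed domtblout line ", bad, " in ", path,
                 ": fewer than 23 whitespace-separated fields"))
  }
  # domtblout columns (1-based): 1 target name, 2 target acc, 4 query name,
  # 5 query acc, 13 i-Evalue, 14 dom score, 20 env from, 21 env to.
  # HMMER output orientation differs between hmmsearch (query = model) and
  # hmmscan (target = model); detect the Pfam accession column.
  col <- function(k) vapply(fields, `[[`, character(1), k)
  tacc <- col(2); qacc <- col(5)
  pf_in <- if (any(grepl("^PF\\d+", qacc))) qacc else tacc
  prot <- if (any(grepl("^PF\\d+", qacc))) col(1) else col(4)
  num <- function(k, label) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) {
      abort(paste0("Malformed domtblout line ", idx[which(is.na(v))[1]],
                   ": non-numeric ", label, " field"))
    }
    v
  }
  i_evalue <- num(13, "i-Evalue")
  bit_score <- num(14, "domain score")
  env_start <- as.integer(num(20, "env from"))
  env_end <- as.integer(num(21, "env to"))
  if (any(i_evalue < 0)) {
    abort(paste0("Malformed domtblout line ", idx[which(i_evalue < 0)[1]],
                 ": negative i-Evalue"))
  }
  hits <- tibble::tibble(protein_id = prot,
                         pfam_acc = normalize_pfam_acc(pf_in),
                         env_start = env_start, env_end = env_end,
                         bit_score = bit_score, i_evalue = i_evalue)
  kept <- hits$i_evalue <= max_i_evalue
  if (any(!kept)) {
    inform(sprintf(
      "read_domtblout: dropped %d of %d hits with i-Evalue > %g",
      sum(!kept), nrow(hits), max_i_evalue))
  }
  hits[kept, ]
}

#' Read a Phobius-style topology table
#'
#' @param path TSV with header columns `protein_id`, `has_sp`, `n_tmd`.
#' @return A tibble. Proteins with more than 4 predicted transmembrane
#'   domains are kept but flagged with a warning, as TMD counts above four
#'   are outside the range seen in surveyed ice-binding proteins.
#' @export
read_topology <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "has_sp", "n_tmd"), "topology")
  df$has_sp <- as.logical(df$has_sp)
  df$n_tmd <- as.integer(df$n_tmd)
  if (any(df$n_tmd < 0, na.rm = TRUE)) abort("topology: negative n_tmd")
  if (any(df$n_tmd > 4, na.rm = TRUE)) {
    warn(sprintf("topology: %d protein(s) with more than 4 TMDs",
                 sum(df$n_tmd > 4, na.rm = TRUE)))
  }
  df
}

#' Read a per-gene, per-sample read-count table
#' @param path TSV with header columns `gene_id`, `sample_id`, `read_count`.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "sample_id", "read_count"),
                         "read counts")
  df$read_count <- as.integer(df$read_count)
  if (any(df$read_count < 0, na.rm = TRUE)) {
    abort("read counts: negative read_count")
  }
  df
}

#' Read a taxonomy assignment table
#'
#' @param path TSV with columns `subject_id` (gene or contig key), rank
#'   columns among `domain`, `phylum`, `class`, `order`, `family`, `genus`
#'   (missing labels empty), and optionally `is_eukaryote`.
#' @return A tibble with an `is_eukaryote` logical column (derived from the
#'   domain rank when not supplied).
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, "subject_id", "taxonomy")
  rank_cols <- intersect(c("domain", "phylum", "class", "order", "family",
                           "genus"), names(df))
  for (rc in rank_cols) {
    df[[rc]][!is.na(df[[rc]]) & df[[rc]] == ""] <- NA_character_
  }
  if (!"is_eukaryote" %in% names(df)) {
    df$is_eukaryote <- if ("domain" %in% names(df)) {
      !is.na(df$domain) & tolower(df$domain) %in% c("eukaryota", "eukarya")
    } else FALSE
  } else {
    df$is_eukaryote <- as.logical(df$is_eukaryote)
  }
  df
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `environment`,
#'   `total_mapped_reads` and optionally `pooled`.
#' @return A tibble; `environment` is validated against the closed
#'   four-class vocabulary (`interior_ice`, `sea_ice_interface`,
#'   `epipelagic`, `meso_bathypelagic`).
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "environment",
                                 "total_mapped_reads"), "sample metadata")
  bad <- setdiff(unique(df$environment), ENVIRONMENTS)
  if (length(bad) > 0) {
    abort(paste0("sample metadata: unknown environment(s): ",
                 paste(bad, collapse = ", "), "; expected one of ",
                 paste(ENVIRONMENTS, collapse = ", ")))
  }
  df$total_mapped_reads <- as.numeric(df$total_mapped_reads)
  if (any(df$total_mapped_reads <= 0)) {
    abort("sample metadata: total_mapped_reads must be positive")
  }
  if (!"pooled" %in% names(df)) df$pooled <- FALSE
  df$pooled <- as.logical(df$pooled)
  df
}

#' Read a MAG membership table
#' @param path TSV with columns `mag_id`, `contig_id` and optional
#'   pass-through columns `completeness`, `contamination`, `taxonomy`.
#' @return A tibble.
#' @export
read_mag_members <- function(path) {
  read_tsv_checked(path, c("mag_id", "contig_id"), "MAG membership")
}

#' Drop genes on short contigs
#'
#' Retains genes whose contig is at least `min_len` base pairs long
#' (boundary inclusive); the assembly filter used throughout is 500 bp.
#'
#' @param genes Gene table from [read_gff()].
#' @param contig_lengths Named numeric vector (or two-column data frame
#'   `contig_id`, `length`) of contig lengths; must cover every contig in
#'   `genes`.
#' @param min_len Minimum contig length in bp (default 500).
#' @return Filtered gene table.
#' @export
filter_contigs <- function(genes, contig_lengths, min_len = 500) {
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- setNames(contig_lengths$length,
                               contig_lengths$contig_id)
  }
  missing <- setdiff(unique(genes$contig_id), names(contig_lengths))
  if (length(missing) > 0) {
    abort(paste0("filter_contigs: no recorded length for contig(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  genes[contig_lengths[genes$contig_id] >= min_len, ]
}

#' Remove genes classified as eukaryotic
#'
#' A gene is removed when its own taxonomy record, or failing that its
#' contig's record, is flagged eukaryotic (gene-level evidence takes
#' precedence over contig-level). Genes with no taxonomy record at all are
#' retained and counted as unclassified.
#'
#' @param genes Gene table.
#' @param taxonomy Taxonomy table from [read_taxonomy()] keyed by gene
#'   and/or contig ids.
#' @return Filtered gene table; the number of unclassified genes is attached
#'   as attribute `n_unclassified`.
#' @export
drop_eukaryotes <- function(genes, taxonomy) {
  if (nrow(taxonomy) == 0) {
    attr(genes, "n_unclassified") <- nrow(genes)
    return(genes)
  }
  euk <- setNames(taxonomy$is_eukaryote, taxonomy$subject_id)
  by_gene <- euk[genes$gene_id]
  by_contig <- euk[genes$contig_id]
  is_euk <- ifelse(!is.na(by_gene), by_gene,
                   ifelse(!is.na(by_contig), by_contig, FALSE))
  out <- genes[!is_euk, ]
  attr(out, "n_unclassified") <-
    sum(is.na(by_gene[!is_euk]) & is.na(by_contig[!is_euk]))
  out
}

#' Gene lengths in base pairs
#' @param genes Gene table.
#' @return Named integer vector of lengths (`end - start + 1`).
#' @export
gene_lengths <- function(genes) {
  setNames(genes$end - genes$start + 1L, genes$gene_id)
}
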