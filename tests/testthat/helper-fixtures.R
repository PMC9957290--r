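# Shared fixture builders; everything is generated in code at test time.

make_hits <- function(protein_id, pfam_acc, env_start, env_end,
                      bit_score = 100, i_evalue = 1e-30) {
  tibble::tibble(protein_id = protein_id, pfam_acc = pfam_acc,
                 env_start = as.integer(env_start),
                 env_end = as.integer(env_end),
                 bit_score = bit_score, i_evalue = i_evalue)
}

make_genes <- function(contig_id, start, end, strand = "+",
                       gene_id = NULL, sample_id = "s1") {
  n <- length(start)
  tibble::tibble(
    gene_id = gene_id %||% sprintf("g%02d", seq_len(n)),
    contig_id = rep_len(contig_id, n), sample_id = rep_len(sample_id, n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(contig, start, end, strand = "+", id = "g1",
                     type = "CDS", attrs = sprintf("ID=%s", id)) {
  sprintf("%s\tsrc\t%s\t%s\t%s\t.\t%s\t0\t%s",
          contig, type, start, end, strand, attrs)
}

# Exhaustive-search oracle for the envelope-overlap selection rule:
# enumerates all pairwise-compatible subsets and returns the best total
# bit score. Compatibility mirrors the documented rule (> max_overlap of
# the shorter envelope is a conflict).
best_compatible_score <- function(hits, max_overlap = 0.5) {
  n <- nrow(hits)
  compat <- function(i, j) {
    ov <- min(hits$env_end[i], hits$env_end[j]) -
      max(hits$env_start[i], hits$env_start[j]) + 1L
    shorter <- min(hits$env_end[i] - hits$env_start[i],
                   hits$env_end[j] - hits$env_start[j]) + 1L
    ov <= max_overlap * shorter
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-1]) {
        for (b in seq_len(a - 1)) {
          if (!compat(idx[a], idx[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(hits$bit_score[idx]))
  }
  best
}

random_hits <- function(n, protein_id = "p1", len = 400) {
  s <- sample.int(len - 60, n, replace = TRUE)
  e <- pmin(s + sample(30:150, n, replace = TRUE), len)
  make_hits(protein_id,
            sample(c("pfam11999", "pfam16130", "pfam07589", "pfam01345"),
                   n, replace = TRUE),
            s, e, bit_score = round(runif(n, 10, 200), 1))
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "ibparch_shared_sim")
      cache <<- simulate_dataset(sim_config(seed = 42), d)
    }
    cache
  }
})
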