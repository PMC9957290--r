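test_that("read_gff preserves 1-based inclusive coordinates and sorts by contig/start", {
  path <- write_gff_fixture(c(
    gff_line("c1", 500, 700, "-", "gB"),
    gff_line("c1", 101, 400, "+", "gA"),
    gff_line("c0", 10, 99, "+", "gC")))
  g <- read_gff(path)
  expect_equal(g$gene_id, c("gC", "gA", "gB"))
  expect_equal(g$end[2] - g$start[2] + 1L, 300L)
  expect_equal(g$strand, c("+", "+", "-"))
})

test_that("read_gff rejects malformed lines with a line number", {
  bad <- write_gff_fixture("c1\tsrc\tCDS\t100")
  expect_error(read_gff(bad), "line 2")
  zero_len <- write_gff_fixture(gff_line("c1", 400, 101))
  expect_error(read_gff(zero_len), "end < start")
  no_id <- write_gff_fixture(gff_line("c1", 1, 30, attrs = "Name=x"))
  expect_error(read_gff(no_id), "ID attribute")
})

write_domtbl <- function(rows) {
  path <- tempfile(fileext = ".domtblout")
  writeLines(c("# comment line", rows), path)
  path
}

dom_row <- function(prot = "p1", acc = "PF11999.6", ieval = "1e-30",
                    score = "150.0", env = c(10, 210)) {
  paste(prot, "-", "300", "DUF3494", acc, "200", "1e-31", "155.0", "0.1",
        "1", "1", "1e-31", ieval, score, "0.1", "1", "200",
        env[1] + 2, env[2] - 2, env[1], env[2], "0.95", "-")
}

test_that("read_domtblout normalizes accessions and applies the i-Evalue threshold", {
  path <- write_domtbl(c(dom_row(acc = "PF11999.6"),
                         dom_row(acc = "PF16130.8", env = c(220, 300)),
                         dom_row(acc = "PF00072.2", ieval = "1.0")))
  h <- read_domtblout(path, max_i_evalue = 1e-5)
  expect_equal(sort(h$pfam_acc), c("pfam11999", "pfam16130"))
  expect_equal(unique(h$protein_id), "p1")  # two hits, one protein
  all_h <- read_domtblout(path, max_i_evalue = Inf)
  expect_equal(nrow(all_h), 3L)  # +Inf retains the file's row count
})

test_that("read_domtblout rejects non-numeric score fields with a line number", {
  path <- write_domtbl(c(dom_row(), dom_row(score = "oops")))
  expect_error(read_domtblout(path), "line 3")
})

test_that("filter_contigs is boundary-inclusive at min_len", {
  g <- make_genes("c1", c(10, 10), c(100, 100), gene_id = c("a", "b"))
  g$contig_id <- c("short", "ok")
  lens <- c(short = 499, ok = 500)
  out <- filter_contigs(g, lens, 500)
  expect_equal(out$gene_id, "b")
  expect_equal(filter_contigs(g, lens, 0), g)  # min_len = 0 is identity
  expect_error(filter_contigs(g, c(short = 499), 500), "ok")
})

test_that("drop_eukaryotes removes by gene or contig record, keeps unclassified", {
  g <- make_genes("c1", c(1, 200, 400), c(90, 290, 490),
                  gene_id = c("gE", "gK", "gU"))
  g$contig_id <- c("c1", "c1", "c2")
  tax <- tibble::tibble(subject_id = c("gE", "c2"),
                        is_eukaryote = c(TRUE, FALSE))
  out <- drop_eukaryotes(g, tax)
  expect_equal(out$gene_id, c("gK", "gU"))
  expect_equal(attr(out, "n_unclassified"), 1L)  # gK has no record at all
  # contig-level flag removes all its genes; gene-level record wins
  tax2 <- tibble::tibble(subject_id = c("c1", "gK"),
                         is_eukaryote = c(TRUE, FALSE))
  expect_equal(drop_eukaryotes(g, tax2)$gene_id, c("gK", "gU"))
  # empty taxonomy is the identity
  empty <- tibble::tibble(subject_id = character(),
                          is_eukaryote = logical())
  expect_equal(drop_eukaryotes(g, empty)$gene_id, g$gene_id)
})

test_that("contig and eukaryote filters are idempotent and commute", {
  sim <- small_sim()
  g <- read_gff(sim$files$gff)
  lens <- read_result_table(sim$files$contigs)
  tax <- read_taxonomy(sim$files$taxonomy)
  f <- function(x) filter_contigs(x, lens, 500)
  e <- function(x) drop_eukaryotes(x, tax)
  fe <- e(f(g)); ef <- f(e(g))
  expect_equal(fe$gene_id, ef$gene_id)
  expect_equal(f(f(g))$gene_id, f(g)$gene_id)
  expect_equal(e(e(g))$gene_id, e(g)$gene_id)
  expect_lt(nrow(fe), nrow(g))  # both filters bite on this dataset
})

test_that("result tables round-trip: integers exactly, reals to 6 significant figures", {
  df <- tibble::tibble(id = c("a", "b"), n = c(3L, 1234567L),
                       x = c(1.2345678901, 98765.4321098))
  path <- tempfile(fileext = ".tsv")
  write_result_table(df, path, config = list(k = 1))
  back <- read_result_table(path)
  expect_identical(back$n, df$n)
  expect_equal(signif(back$x, 6), signif(df$x, 6))
  header <- readLines(path, n = 1)
  expect_match(header, "^# ibparch .*config=")
})

test_that("topology reader flags proteins with more than four TMDs", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\thas_sp\tn_tmd", "p1\tTRUE\t2", "p2\tFALSE\t6"),
             path)
  expect_warning(tp <- read_topology(path), "more than 4 TMDs")
  expect_equal(tp$n_tmd, c(2L, 6L))  # flagged but kept
})

test_that("sample metadata enforces the closed environment vocabulary", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tenvironment\ttotal_mapped_reads",
               "s1\tbenthic\t1000"), path)
  expect_error(read_sample_meta(path), "unknown environment")
})
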