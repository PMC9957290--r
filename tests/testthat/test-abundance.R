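test_that("rpkm matches its closed form and rejects degenerate inputs", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 777, 123456), 0)
  expect_equal(rpkm(25, 500, 2e6), 25)  # 25 / 0.5 / 2
  expect_error(rpkm(1, 0, 1e6), "gene_length_bp")
  expect_error(rpkm(1, 100, 0), "total_mapped_reads")
  expect_error(rpkm(-1, 100, 1e6), "negative")
})

test_that("rpkm is linear in reads and inversely proportional to length", {
  grid <- expand.grid(r = c(1, 7, 100, 12345),
                      L = c(150, 999, 10000),
                      Tm = c(1e5, 1e6, 2.5e7))
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; L <- grid$L[i]; Tm <- grid$Tm[i]
    expect_equal(rpkm(2 * r, L, Tm), 2 * rpkm(r, L, Tm),
                 tolerance = 1e-12)
    expect_equal(rpkm(r, 2 * L, Tm), rpkm(r, L, Tm) / 2,
                 tolerance = 1e-12)
    expect_equal(rpkm(r, L, 2 * Tm), rpkm(r, L, Tm) / 2,
                 tolerance = 1e-12)
  }
})

mini_arch <- function(arch_strings, gene_ids = NULL, loc = "none",
                      env = NULL, ord = NULL) {
  n <- length(arch_strings)
  out <- tibble::tibble(
    gene_id = gene_ids %||% sprintf("g%03d", seq_len(n)),
    arch_string = arch_strings,
    localization_class = rep_len(loc, n))
  if (!is.null(env)) out$environment <- env
  if (!is.null(ord)) out$order <- ord
  out
}

test_that("aggregate_architectures computes abundance and prevalence shares", {
  arch <- mini_arch(c("A", "A", "A", "A", "B"))
  rk <- tibble::tibble(gene_id = arch$gene_id,
                       rpkm = c(25, 25, 15, 10, 25))
  ab <- aggregate_architectures(arch, rk)
  expect_equal(ab$pct_abundance, c(75, 25))
  expect_equal(ab$pct_prevalence, c(80, 20))
  expect_equal(sum(ab$pct_abundance), 100, tolerance = 0.01)
  expect_equal(sum(ab$n_genes), nrow(arch))
  expect_error(aggregate_architectures(arch, rk[-1, ]), "g001")
})

test_that("a single high-RPKM gene ranks high in abundance but low in prevalence", {
  arch <- mini_arch(c("rare_rich", rep("common_poor", 99)))
  rk <- tibble::tibble(gene_id = arch$gene_id, rpkm = c(900, rep(1, 99)))
  ab <- aggregate_architectures(arch, rk)
  expect_equal(ab$arch_string[1], "rare_rich")  # ranked by RPKM
  expect_gt(ab$pct_abundance[1], 90)
  expect_equal(ab$pct_prevalence[1], 1)
})

test_that("percent tables are invariant under uniform RPKM scaling", {
  arch <- mini_arch(rep(c("A", "B", "C"), times = c(5, 3, 2)))
  rk <- tibble::tibble(gene_id = arch$gene_id, rpkm = runif(10, 1, 50))
  ab1 <- aggregate_architectures(arch, rk)
  rk2 <- rk; rk2$rpkm <- rk2$rpkm * 1234.5
  ab2 <- aggregate_architectures(arch, rk2)
  expect_equal(ab1$pct_abundance, ab2$pct_abundance, tolerance = 1e-12)
  expect_equal(ab1$pct_prevalence, ab2$pct_prevalence)
})

test_that("aggregate ranking breaks RPKM ties by architecture string", {
  arch <- mini_arch(c("zzz", "aaa"))
  rk <- tibble::tibble(gene_id = arch$gene_id, rpkm = c(10, 10))
  expect_equal(aggregate_architectures(arch, rk)$arch_string,
               c("aaa", "zzz"))
})

test_that("environment breakdown reports 2-dp percentages that sum to 100", {
  pc <- environment_breakdown(c(a = 2, b = 1, c = 1))
  expect_equal(unname(pc), c(50, 25, 25))
  expect_equal(unname(environment_breakdown(c(x = 1, y = 0))), c(100, 0))
  expect_error(environment_breakdown(c(a = 0, b = 0)), "zero")
})

test_that("localization breakdown enumerates SP/TMD classes", {
  arch <- tibble::tibble(
    arch_string = "pfam11999",
    has_sp = c(TRUE, FALSE, TRUE),
    n_tmd = c(0L, 1L, 1L),
    localization_class = c("sp_only", "tmd_only", "both"))
  lb <- localization_breakdown(arch)
  got <- setNames(lb$classes$pct, lb$classes$class)
  expect_equal(unname(got[c("sp_only", "tmd_only", "both")]),
               rep(33.33, 3))
  expect_equal(unname(got["none"]), 0)
  expect_equal(lb$pct_both, 33.33)

  none <- tibble::tibble(arch_string = "x", has_sp = FALSE, n_tmd = 0L,
                         localization_class = "none")
  expect_equal(localization_breakdown(none)$pct_neither, 100)
  expect_warning(localization_breakdown(none[0, ]), "empty subset")
})

test_that("planted Bernoulli SP rate is recovered within binomial error", {
  set.seed(11)
  n <- 10000
  has_sp <- runif(n) < 0.4
  arch <- tibble::tibble(
    arch_string = "pfam11999", has_sp = has_sp,
    n_tmd = 0L,
    localization_class = ifelse(has_sp, "sp_only", "none"))
  lb <- localization_breakdown(arch)
  se3 <- 3 * sqrt(0.4 * 0.6 / n) * 100
  expect_lt(abs(lb$pct_sp - 40), se3)
})

test_that("taxon breakdown tallies unclassified separately", {
  ord <- c(rep("Alteromonadales", 51), rep("Flavobacteriales", 17),
           rep("Cellvibrionales", 6), "Vibrionales",
           rep(NA_character_, 11))
  arch <- mini_arch(rep("pfam11999_pfam16130", length(ord)), ord = ord)
  tb <- taxon_breakdown(arch, "order")
  expect_equal(tb$n_classified, 75L)
  expect_equal(tb$taxa$n[1], 51L)
  expect_equal(sum(tb$taxa$n), tb$n_classified)
  expect_error(taxon_breakdown(arch, "species"), "rank")
  noinfo <- mini_arch("a", ord = NA_character_)
  expect_equal(taxon_breakdown(noinfo, "order")$pct_classified, 0)
})
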