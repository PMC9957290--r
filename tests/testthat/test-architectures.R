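test_that("resolve_overlaps keeps disjoint hits and dominant scores", {
  h <- make_hits("p1", c("pfam11999", "pfam16130"), c(10, 220),
                 c(210, 300))
  expect_equal(nrow(resolve_overlaps(h)), 2L)
  dup <- make_hits("p1", c("pfam11999", "pfam16130"), c(10, 10),
                   c(210, 210), bit_score = c(80, 40))
  kept <- resolve_overlaps(dup)
  expect_equal(kept$pfam_acc, "pfam11999")
  expect_equal(kept$bit_score, 80)
})

test_that("resolve_overlaps is feasible, maximal and score-competitive with exhaustive search", {
  set.seed(101)
  agree <- 0L
  for (rep in 1:25) {
    h <- random_hits(sample(3:8, 1))
    kept <- resolve_overlaps(h)
    # feasibility: no retained pair violates the overlap rule
    if (nrow(kept) > 1) {
      for (a in 2:nrow(kept)) for (b in 1:(a - 1)) {
        ov <- min(kept$env_end[a], kept$env_end[b]) -
          max(kept$env_start[a], kept$env_start[b]) + 1L
        shorter <- min(kept$env_end[a] - kept$env_start[a],
                       kept$env_end[b] - kept$env_start[b]) + 1L
        expect_lte(ov, 0.5 * shorter)
      }
    }
    best <- best_compatible_score(h)
    expect_lte(sum(kept$bit_score), best + 1e-9)
    if (abs(sum(kept$bit_score) - best) < 1e-9) agree <- agree + 1L
  }
  # greedy-by-score matches the exhaustive optimum in most random cases;
  # residual disagreements are an accepted property of the greedy rule
  expect_gt(agree, 15L)
})

test_that("architecture strings are invariant to input hit order", {
  set.seed(7)
  h <- make_hits("p1", c("pfam13205", "pfam13205", "pfam11999"),
                 c(5, 120, 260), c(100, 215, 460),
                 bit_score = c(60, 55, 200))
  ref <- build_architecture(resolve_overlaps(h))
  for (i in 1:10) {
    perm <- h[sample.int(nrow(h)), ]
    expect_equal(build_architecture(resolve_overlaps(perm))$arch_string,
                 ref$arch_string)
  }
  expect_equal(ref$arch_string, "pfam13205_pfam13205_pfam11999")
  expect_equal(ref$n_nterm, 2L)
  expect_equal(ref$n_cterm, 0L)
})

test_that("build_architecture derives copy counts and the N/C split at the first target copy", {
  single <- build_architecture(make_hits("p1", "pfam11999", 10, 210))
  expect_equal(single$arch_string, "pfam11999")
  expect_equal(single$n_target, 1L)

  dd <- build_architecture(make_hits(
    "p2", c("pfam11999", "pfam16130"), c(5, 220), c(200, 300)))
  expect_equal(dd$arch_string, "pfam11999_pfam16130")
  expect_equal(dd$n_cterm, 1L)
  expect_equal(dd$n_nterm, 0L)

  td <- build_architecture(make_hits(
    "p3", rep("pfam11999", 3), c(5, 230, 460), c(200, 430, 660)))
  expect_equal(td$arch_string, "pfam11999_pfam11999_pfam11999")
  expect_equal(td$n_target, 3L)

  # companion interleaved between target copies counts as C-terminal
  inter <- build_architecture(make_hits(
    "p4", c("pfam11999", "pfam01345", "pfam11999"),
    c(5, 210, 320), c(200, 310, 520)))
  expect_equal(inter$n_nterm, 0L)
  expect_equal(inter$n_cterm, 1L)
  expect_equal(inter$n_nterm + inter$n_cterm + inter$n_target,
               inter$n_domains)
  expect_error(build_architecture(make_hits("p5", "pfam16130", 1, 100)),
               "no pfam11999")
})

test_that("the two diversity definitions differ exactly on SP/TMD-only proteins", {
  arch <- tibble::tibble(n_domains = c(1L, 1L, 2L),
                         has_sp = c(FALSE, TRUE, FALSE),
                         n_tmd = c(0L, 0L, 0L))
  expect_equal(classify_diverse(arch, "results"), c(FALSE, FALSE, TRUE))
  expect_equal(classify_diverse(arch, "methods"), c(FALSE, TRUE, TRUE))
  expect_error(classify_diverse(arch, "paper"), "mode")
})

test_that("annotate_function maps companions and labels unknown accessions unmapped", {
  arch <- dplyr::bind_rows(
    build_architecture(make_hits("p1", c("pfam11999", "pfam16130"),
                                 c(5, 220), c(200, 300))),
    build_architecture(make_hits("p2", c("pfam11999", "pfam07589"),
                                 c(5, 220), c(200, 300))),
    build_architecture(make_hits("p3", c("pfam11999", "pfam99999"),
                                 c(5, 220), c(200, 300))))
  ann <- annotate_function(arch)
  expect_equal(ann$broad_functions,
               c("β-barrel Ig fold", "Sorting/Exopolysaccharides",
                 "unmapped"))
  expect_equal(ann$has_ig_like, c(TRUE, FALSE, FALSE))
  expect_equal(ann$family_names[1], "DUF4842")
})

test_that("every protein with a retained target hit yields exactly one architecture", {
  sim <- small_sim()
  hits <- read_domtblout(sim$files$domtblout)
  topo <- read_topology(sim$files$topology)
  arch <- build_architectures(hits, topo)
  target_prot <- unique(hits$protein_id[hits$pfam_acc == "pfam11999"])
  expect_setequal(arch$gene_id, target_prot)
  expect_equal(anyDuplicated(arch$gene_id), 0L)
  # localization classes partition the catalogue
  expect_equal(sum(table(arch$localization_class)), nrow(arch))
  expect_true(all(arch$localization_class %in%
                    c("none", "sp_only", "tmd_only", "both")))
})

test_that("missing topology records default to no SP and no TMD", {
  h <- make_hits("p1", "pfam11999", 10, 210)
  a <- suppressMessages(build_architectures(h, topology = NULL))
  expect_false(a$has_sp)
  expect_equal(a$n_tmd, 0L)
  expect_equal(a$localization_class, "none")
})
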