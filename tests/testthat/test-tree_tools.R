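test_that("excise_domains slices envelopes and names records id/start-end", {
  seqs <- Biostrings::AAStringSet(c(
    p1 = paste(rep("A", 300), collapse = ""),
    p2 = paste(rep("C", 500), collapse = "")))
  hits <- make_hits(c("p1", "p2", "p2"), "pfam11999",
                    c(10, 5, 240), c(210, 204, 439))
  out <- excise_domains(seqs, hits)
  expect_equal(length(out), 3L)
  expect_equal(Biostrings::width(out)[1], 201L)
  expect_setequal(names(out), c("p1/10-210", "p2/5-204", "p2/240-439"))
  bad <- make_hits("p1", "pfam11999", 150, 301)
  expect_error(excise_domains(seqs, bad), "beyond sequence end")
  # only target-domain hits are excised
  mixed <- rbind(hits, make_hits("p1", "pfam16130", 220, 290))
  expect_equal(length(excise_domains(seqs, mixed)), 3L)
})

tip_depths <- function(tree) {
  d <- ape::dist.nodes(tree)
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  vapply(kids, function(k) {
    tips <- if (k <= ape::Ntip(tree)) k else
      which(tree$tip.label %in% ape::extract.clade(tree, k)$tip.label)
    max(d[root, tips])
  }, numeric(1))
}

test_that("midpoint rooting balances the two root-adjacent depths", {
  tr <- ape::read.tree(text = "(A:1,(B:2,C:3):1);")
  rooted <- root_tree(tr, min_leaves_for_outgroup = 60)
  expect_equal(attr(rooted, "rooting"), "midpoint")
  depths <- tip_depths(rooted)
  expect_equal(depths[1], depths[2], tolerance = 1e-9)
  expect_equal(max(depths), 2.5)  # half the 5-unit B-C diameter
  # idempotence
  again <- root_tree(rooted, min_leaves_for_outgroup = 60)
  expect_equal(ape::cophenetic.phylo(again)[c("A", "B", "C"),
                                            c("A", "B", "C")],
               ape::cophenetic.phylo(rooted)[c("A", "B", "C"),
                                             c("A", "B", "C")],
               tolerance = 1e-12)
})

test_that("rooting preserves the leaf set and path-length matrix", {
  set.seed(41)
  for (i in 1:10) {
    tr <- ape::rtree(15)
    rooted <- root_tree(tr, min_leaves_for_outgroup = 60)
    expect_setequal(rooted$tip.label, tr$tip.label)
    labs <- sort(tr$tip.label)
    expect_equal(ape::cophenetic.phylo(rooted)[labs, labs],
                 ape::cophenetic.phylo(tr)[labs, labs],
                 tolerance = 1e-9)
    expect_equal(sum(rooted$edge.length), sum(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("outgroup rooting places the root on the edge subtending the outgroup clade", {
  set.seed(42)
  ingroup <- ape::rtree(90)
  outgroup <- ape::rtree(10)
  outgroup$tip.label <- sprintf("og%02d", 1:10)
  tr <- ape::read.tree(text = paste0(
    "(", sub(";$", "", ape::write.tree(ingroup)), ":1,",
    sub(";$", "", ape::write.tree(outgroup)), ":1);"))
  tr <- ape::unroot(tr)
  rooted <- root_tree(tr, outgroup_leaf_ids = outgroup$tip.label,
                      min_leaves_for_outgroup = 60)
  expect_equal(attr(rooted, "rooting"), "outgroup")
  root <- ape::Ntip(rooted) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k) {
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k] else
      ape::extract.clade(rooted, k)$tip.label
  })
  og_side <- vapply(sides, function(s)
    all(s %in% outgroup$tip.label) && length(s) == 10, logical(1))
  expect_true(any(og_side))  # one root child is exactly the outgroup
  labs <- sort(tr$tip.label)
  expect_equal(ape::cophenetic.phylo(rooted)[labs, labs],
               ape::cophenetic.phylo(tr)[labs, labs], tolerance = 1e-9)
})

test_that("the rooting rule falls back to midpoint for small or multi-copy trees", {
  set.seed(43)
  tr <- ape::rtree(30)
  r1 <- root_tree(tr, outgroup_leaf_ids = tr$tip.label[1:3],
                  min_leaves_for_outgroup = 60)
  expect_equal(attr(r1, "rooting"), "midpoint")
  big <- ape::rtree(70)
  r2 <- root_tree(big, outgroup_leaf_ids = big$tip.label[1:4],
                  min_leaves_for_outgroup = 60, multi_copy = TRUE)
  expect_equal(attr(r2, "rooting"), "midpoint")
  expect_error(root_tree(big, outgroup_leaf_ids = c("zz1", "zz2"),
                         min_leaves_for_outgroup = 60),
               "no outgroup leaf")
})

test_that("iTOL export writes one dataset file per ring with white unknowns", {
  tr <- ape::read.tree(text = "(leafA:1,leafB:1);")
  ann <- tibble::tibble(
    leaf_id = c("leafA", "leafB"),
    environment = c("interior_ice", "epipelagic"),
    order = c("Flavobacteriales", NA),
    arch_class = c("single", "double"),
    abundance_rpkm = c(12.5, 0.75))
  dir <- tempfile("itol_")
  files <- export_itol_rings(tr, ann, dir)
  expect_true(all(file.exists(files)))
  env <- readLines(file.path(dir, "itol_environment.txt"))
  expect_equal(sum(grepl("^leaf", env)), 2L)
  ord <- readLines(file.path(dir, "itol_order.txt"))
  expect_match(ord[grepl("leafB", ord)], "#ffffff")  # unknown = white
  bar <- readLines(file.path(dir, "itol_abundance.txt"))
  expect_match(bar[grepl("leafA", bar)], "12.5")
  dup <- rbind(ann, ann[1, ])
  expect_error(export_itol_rings(tr, dup, dir), "duplicate")
})

test_that("arch_class uses the closed ring vocabulary", {
  expect_equal(
    arch_class(c("pfam11999", "pfam11999_pfam11999",
                 "pfam11999_pfam11999_pfam11999",
                 "pfam11999_pfam16130", "pfam11999_pfam07589",
                 "pfam11999_pfam01345")),
    c("single", "double", "triple", "duf4842", "pep_cterm", "other"))
})
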