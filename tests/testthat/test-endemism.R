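test_that("Newick parsing validates structure and accepts polytomies", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)
  expect_equal(sum(tr$edge.length), 5)

  poly <- read_newick("((A:1,B:1,C:1):1,D:2);")
  expect_equal(length(poly$tip.label), 4L)
  expect_equal(poly$Nnode, 2L)  # degree-3 polytomy kept

  expect_error(read_newick("((A:1,B:1;"), "parse")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick("((A,B),C);"), "branch lengths")

  rt <- read_newick(write_newick(tr))
  expect_equal(rt$tip.label, tr$tip.label)
  expect_equal(rt$edge.length, tr$edge.length)
})

test_that("branch ranges are unions of descendant tip ranges", {
  # ((A,B),C) with A in c1, B in c1+c2, C in c3
  tr <- read_newick("((A:1,B:1):1,C:2);")
  cells <- data.frame(id = c("c1", "c2", "c3"), x = 1:3, y = 0)
  pres <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), cells$id))
  pres["A", "c1"] <- 1; pres["B", c("c1", "c2")] <- 1; pres["C", "c3"] <- 1
  g <- occurrence_grid(pres, cells)
  br <- branch_ranges(tr, g)
  ab_edge <- which(tr$edge[, 2] == length(tr$tip.label) + 2L)  # (A,B) clade
  expect_setequal(br$cells[[ab_edge]], c("c1", "c2"))
  expect_equal(br$range_size[ab_edge], 2L)
  # tip branches: range equals the species range
  a_edge <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  expect_equal(br$cells[[a_edge]], "c1")

  missing_tip <- read_newick("((A:1,Z:1):1,C:2);")
  expect_error(branch_ranges(missing_tip, g), "absent from grid")
})

test_that("branch ranges match brute-force union enumeration on random instances", {
  set.seed(33)
  for (rep in 1:5) {
    inst <- random_instance(n_tip = 6, n_cell = 5)
    br <- branch_ranges(inst$tree, inst$grid)
    for (e in seq_len(nrow(inst$tree$edge))) {
      tips <- inst$tree$tip.label[
        oracle_descendant_tips(inst$tree, inst$tree$edge[e, 2])]
      expected <- colnames(inst$presence)[
        colSums(inst$presence[tips, , drop = FALSE]) > 0]
      expect_setequal(br$cells[[e]], expected)
    }
  }
})

test_that("PE matches the hand-worked cherry example", {
  # cherry (A:1,B:1); A in c1, B in c1+c2
  tr <- read_newick("(A:1,B:1);")
  cells <- data.frame(id = c("c1", "c2"), x = 1:2, y = 0)
  pres <- matrix(0, 2, 2, dimnames = list(c("A", "B"), cells$id))
  pres["A", "c1"] <- 1; pres["B", c("c1", "c2")] <- 1
  g <- occurrence_grid(pres, cells)
  pe_u <- phylogenetic_endemism(tr, g, scaled = FALSE)
  expect_equal(unname(pe_u), c(1 / 1 + 1 / 2, 1 / 2))
  pe_s <- phylogenetic_endemism(tr, g, scaled = TRUE)
  expect_equal(unname(pe_s), c(0.75, 0.25))
})

test_that("scaled PE is 1/n_cells everywhere when every species fills the grid", {
  tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  cells <- data.frame(id = sprintf("c%d", 1:4), x = 1:4, y = 0)
  pres <- matrix(1, 5, 4, dimnames = list(tr$tip.label, cells$id))
  g <- occurrence_grid(pres, cells)
  expect_equal(unname(phylogenetic_endemism(tr, g, scaled = TRUE)),
               rep(1 / 4, 4))
})

test_that("PE, PE_equal and RPE match the brute-force oracle", {
  set.seed(77)
  for (rep in 1:10) {
    inst <- random_instance(n_tip = 8, n_cell = 6)
    em <- endemism_metrics(inst$tree, inst$grid, scaled = TRUE)
    orc <- oracle_metrics(inst$tree, inst$presence, scaled = TRUE)
    expect_equal(em$PE_original, unname(orc$PE_original), tolerance = 1e-12)
    expect_equal(em$PE_equal, unname(orc$PE_equal), tolerance = 1e-12)
    expect_equal(em$RPE, unname(orc$RPE), tolerance = 1e-12)
  }
})

test_that("PE conservation: unscaled PE sums to total gridded branch length", {
  set.seed(101)
  for (rep in 1:10) {
    inst <- random_instance(n_tip = sample(4:10, 1), n_cell = sample(3:8, 1))
    pe <- phylogenetic_endemism(inst$tree, inst$grid, scaled = FALSE)
    expect_equal(sum(pe), sum(inst$tree$edge.length), tolerance = 1e-9)
    expect_equal(sum(phylogenetic_endemism(inst$tree, inst$grid, scaled = TRUE)),
                 1, tolerance = 1e-9)
  }
})

test_that("PE is monotone under added presences within a cell", {
  set.seed(55)
  inst <- random_instance(n_tip = 7, n_cell = 5)
  pe0 <- phylogenetic_endemism(inst$tree, inst$grid, scaled = FALSE)
  pres2 <- inst$presence
  absent <- which(pres2 == 0, arr.ind = TRUE)
  add <- absent[sample.int(nrow(absent), 1), ]
  pres2[add[1], add[2]] <- 1
  g2 <- occurrence_grid(pres2, inst$grid$cells)
  pe1 <- phylogenetic_endemism(inst$tree, g2, scaled = FALSE)
  cell_changed <- colnames(pres2)[add[2]]
  expect_gte(pe1[cell_changed] + 1e-12, pe0[cell_changed])
})

test_that("equalize_branch_lengths preserves topology and total length", {
  tr <- read_newick("(A:1,B:2,C:3);")
  eq <- equalize_branch_lengths(tr)
  expect_equal(eq$edge.length, rep(2, 3))
  expect_equal(sum(eq$edge.length), sum(tr$edge.length))
  expect_identical(eq$edge, tr$edge)
  expect_identical(eq$tip.label, tr$tip.label)
  # already equal in expectation: fixed point
  expect_equal(equalize_branch_lengths(eq)$edge.length, eq$edge.length)

  set.seed(8)
  big <- ape::rtree(10, br = function(n) runif(n, 0.1, 3))
  eq2 <- equalize_branch_lengths(big)
  expect_equal(sum(eq2$edge.length), sum(big$edge.length), tolerance = 1e-12)
  expect_equal(length(unique(round(eq2$edge.length, 12))), 1L)
})

test_that("RPE is 1 everywhere on an equal-branch-length tree", {
  set.seed(13)
  inst <- random_instance(n_tip = 6, n_cell = 5)
  eq <- equalize_branch_lengths(inst$tree)
  em <- endemism_metrics(eq, inst$grid)
  occupied <- richness(inst$grid) > 0
  expect_equal(em$RPE[occupied], rep(1, sum(occupied)), tolerance = 1e-12)
  expect_true(all(is.na(em$RPE[!occupied])))

  # cherry with equal branches: comparison tree identical
  tr <- read_newick("(A:1,B:1);")
  cells <- data.frame(id = c("c1", "c2"), x = 1:2, y = 0)
  pres <- matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(c("A", "B"), cells$id))
  em2 <- endemism_metrics(tr, occurrence_grid(pres, cells))
  expect_equal(em2$RPE, c(1, 1))
})

test_that("long-branch concentration raises RPE where old endemics live", {
  # A and B are recent (short terminal branches under a long stem), C is an
  # old isolated lineage; c1 holds A+C, c2 holds B+C
  tr <- read_newick("((A:0.1,B:0.1):1.8,C:2);")
  cells <- data.frame(id = c("c1", "c2"), x = 1:2, y = 0)
  pres <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), cells$id))
  pres["A", "c1"] <- 1; pres["B", "c2"] <- 1; pres["C", c("c1", "c2")] <- 1
  g <- occurrence_grid(pres, cells)
  em <- endemism_metrics(tr, g)
  orc <- oracle_metrics(tr, pres)
  expect_equal(em$RPE, unname(orc$RPE), tolerance = 1e-12)
  # symmetric ranges here: both cells hold one short-branch endemic plus C
  expect_equal(em$RPE[1], em$RPE[2], tolerance = 1e-12)

  # now restrict the old lineage to c1 only: c1 must carry higher RPE
  pres["C", "c2"] <- 0
  pres["B", "c1"] <- 1  # keep c1/c2 richness comparable
  em2 <- endemism_metrics(tr, occurrence_grid(pres, cells))
  expect_gt(em2$RPE[em2$cell == "c1"], em2$RPE[em2$cell == "c2"])
  orc2 <- oracle_metrics(tr, pres)
  expect_equal(em2$RPE, unname(orc2$RPE), tolerance = 1e-12)
})

test_that("zero total length cannot be scaled", {
  tr <- read_newick("(A:0,B:0);")
  cells <- data.frame(id = "c1", x = 0, y = 0)
  pres <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "c1"))
  g <- occurrence_grid(pres, cells)
  expect_error(phylogenetic_endemism(tr, g, scaled = TRUE), "zero")
  expect_equal(unname(phylogenetic_endemism(tr, g, scaled = FALSE)), 0)
})
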