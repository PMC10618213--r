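test_that("birth-death simulation is seeded, ultrametric, and sized", {
  t1 <- simulate_phylogeny(12, birth = 1, seed = 9)
  t2 <- simulate_phylogeny(12, birth = 1, seed = 9)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(t1$tip.label), 12L)
  depths <- ape::node.depth.edgelength(t1)[1:12]
  expect_lt(diff(range(depths)), 1e-6)     # ultrametric
  expect_true(all(t1$edge.length >= 0))

  t3 <- simulate_phylogeny(2, birth = 1, seed = 1)
  expect_equal(length(t3$tip.label), 2L)   # a single cherry
  expect_equal(t3$Nnode, 1L)

  expect_error(simulate_phylogeny(10, birth = 1, death = 2), "birth > death")
})

test_that("Yule crown depth matches the closed-form harmonic expectation", {
  # stop-at-n construction: crown depth = sum of Exp(k*b), k = 2..n,
  # so E[depth] = (H_n - 1)/b and Var = sum 1/(k b)^2
  n <- 40; b <- 2; reps <- 300
  mu <- (sum(1 / (1:n)) - 1) / b
  sdev <- sqrt(sum(1 / ((2:n) * b)^2))
  set.seed(43)
  depths <- vapply(seq_len(reps), function(i) {
    tr <- simulate_phylogeny(n, birth = b)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expect_lt(abs(mean(depths) - mu), 4 * sdev / sqrt(reps))
})

test_that("scenario trees carry the planted branch-length structure", {
  spec <- small_scenario()
  tr <- scenario_tree(spec, seed = 3)
  expect_equal(length(tr$tip.label),
               spec$n_background + spec$n_paleo + spec$n_neo + spec$n_mixed)
  term <- terminal_branch_lengths(tr)
  paleo <- term[grep("^paleo", names(term))]
  bg <- term[grep("^bg", names(term))]
  neo <- term[grep("^neo", names(term))]
  expect_equal(unname(paleo), rep(1, spec$n_paleo))  # isolated root pendants
  expect_gt(mean(paleo), 3 * mean(bg))               # planted factor
  expect_lt(max(neo), spec$neo_depth + 1e-9)         # recent radiation
  # ultrametric overall at depth 1
  d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(d)), 1e-6)
  expect_equal(max(d), 1, tolerance = 1e-6)
})

test_that("ranges are rook-connected, block-confined for endemics, heavy-tailed", {
  spec <- small_scenario()
  tr <- scenario_tree(spec, seed = 5)
  g <- simulate_ranges(tr, spec, seed = 6)
  expect_true(all(range_sizes(g) >= 1))

  # rook connectivity of every species' range
  nx <- spec$nx
  idx_of <- setNames(seq_len(nrow(g$cells)), g$cells$id)
  for (sp in rownames(g$presence)) {
    occ <- idx_of[colnames(g$presence)[g$presence[sp, ] > 0]]
    if (length(occ) == 1L) next
    adj <- outer(occ, occ, function(a, b) {
      (abs(a - b) == nx) | (abs(a - b) == 1 & ((a - 1) %/% nx == (b - 1) %/% nx))
    })
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj,
                                                                   "undirected"))
    expect_equal(comp$no, 1L)
  }

  # planted species stay inside their refugium block
  blk <- phyloendemism:::block_cells(spec$blocks$paleo, nx)
  blk_ids <- g$cells$id[blk]
  for (sp in grep("^paleo", rownames(g$presence), value = TRUE)) {
    occ <- colnames(g$presence)[g$presence[sp, ] > 0]
    expect_true(all(occ %in% blk_ids))
    expect_lte(length(occ), spec$planted_range_max)
  }

  # background range sizes follow the stated lognormal (KS on a larger draw)
  spec_big <- scenario_spec(nx = 25, ny = 25, n_background = 150)
  tr_big <- scenario_tree(spec_big, seed = 7)
  g_big <- simulate_ranges(tr_big, spec_big, seed = 8)
  rs <- range_sizes(g_big)[grep("^bg", rownames(g_big$presence))]
  ks <- suppressWarnings(
    ks.test(rs, function(q) plnorm(q, spec_big$range_meanlog,
                                   spec_big$range_sdlog)))
  expect_gt(ks$p.value, 0.01)

  expect_error(validate_scenario_capacity <- scenario_spec(
    nx = 20, ny = 20, paleo_block = c(1, 1, 1, 2), planted_range_max = 3),
    "capacity")
})

test_that("environmental fields carry the stated autocorrelation length", {
  spec <- scenario_spec(nx = 28, ny = 28, env_corr_length = 3)
  layers <- simulate_env_layers(spec, seed = 11)
  cells <- lattice_cells(28, 28)
  # empirical correlation at distance d, averaged over 6 independent fields;
  # the range (distance where correlation crosses 1/e) must sit within 25%
  # of the spec value
  d <- as.matrix(dist(cells[, c("x", "y")]))
  fields <- lapply(1:6, function(i)
    simulate_env_layers(spec, seed = 100 + i)$MAT)
  corr_at <- function(lo, hi) {
    sel <- d > lo & d <= hi
    mean(vapply(fields, function(f) {
      z <- f - mean(f)
      idx <- which(sel, arr.ind = TRUE)
      sum(z[idx[, 1]] * z[idx[, 2]]) / (nrow(idx) * stats::var(z) *
                                          (length(z) - 1) / length(z))
    }, numeric(1)))
  }
  lags <- seq(0.5, 8.5, by = 1)
  emp <- vapply(seq_along(lags[-1]), function(i)
    corr_at(lags[i], lags[i + 1]), numeric(1))
  mids <- (lags[-1] + lags[-length(lags)]) / 2
  crossing <- mids[min(which(emp < exp(-1)))]
  expect_lt(abs(crossing - spec$env_corr_length),
            0.25 * spec$env_corr_length + 0.5)  # half a lag of bin resolution

  # hotspot offsets are recoverable as group-mean differences
  hot <- names(layers$MAT) %in% attr(layers, "hotspot_cells")
  for (nm in names(layers)) {
    off <- spec$offsets[[nm]][["offset"]]
    gap <- mean(layers[[nm]][hot]) - mean(layers[[nm]][!hot])
    expect_lt(abs(gap - off), 1.1)   # block means fluctuate under spatial correlation
  }
})

test_that("zero offsets give non-significant hotspot contrasts, 1-sd offsets are detected", {
  # the null check runs at a short correlation length: group-label
  # permutation assumes exchangeability, and strongly autocorrelated fields
  # inflate its type-I error (documented limitation of the naive test)
  base <- scenario_spec(nx = 22, ny = 22)
  flat <- base$offsets
  for (nm in names(flat)) flat[[nm]]["offset"] <- 0
  raised <- flat
  raised$HMI["offset"] <- 1
  null_spec <- scenario_spec(nx = 22, ny = 22, offsets = flat,
                             env_corr_length = 0.5)
  alt_spec <- scenario_spec(nx = 22, ny = 22, offsets = raised)

  null_rejections <- 0L
  power_hits <- 0L
  reps <- 10L
  for (i in seq_len(reps)) {
    lay0 <- simulate_env_layers(null_spec, seed = 200 + i)
    hot0 <- names(lay0$HMI) %in% attr(lay0, "hotspot_cells")
    p0 <- fisher_pitman_two_sample(lay0$HMI[hot0], lay0$HMI[!hot0],
                                   n_perm = 600, seed = i)$p_value
    if (p0 <= 0.05) null_rejections <- null_rejections + 1L
    lay1 <- simulate_env_layers(alt_spec, seed = 300 + i)
    hot1 <- names(lay1$HMI) %in% attr(lay1, "hotspot_cells")
    p1 <- fisher_pitman_two_sample(lay1$HMI[hot1], lay1$HMI[!hot1],
                                   n_perm = 600, seed = i)$p_value
    if (p1 <= 0.05) power_hits <- power_hits + 1L
  }
  expect_lte(null_rejections, 3L)   # null holds in >= 70% of draws
  expect_gte(power_hits, 9L)        # 1-sd offset detected with power >= 0.9
})

test_that("protection masks hit the stated coverage and favour diversity", {
  spec <- small_scenario()
  tr <- scenario_tree(spec, seed = 13)
  g <- simulate_ranges(tr, spec, seed = 14)
  pr <- simulate_protection(spec, g, seed = 15)
  n <- nrow(g$cells)
  expect_equal(sum(pr$existing$protected), ceiling(spec$pa_coverage * n))
  expect_equal(sum(pr$top17$protected), ceiling(0.17 * n))
  # nesting
  expect_true(all(names(pr$top17$protected)[pr$top17$protected] %in%
                  names(pr$top30$protected)[pr$top30$protected]))
  expect_true(all(names(pr$top30$protected)[pr$top30$protected] %in%
                  names(pr$top50$protected)[pr$top50$protected]))

  # priority ranking covers planted blocks better than a random ranking
  blk_ids <- unlist(lapply(spec$blocks, function(b)
    g$cells$id[phyloendemism:::block_cells(b, spec$nx)]))
  prio_cov <- mean(pr$top30$protected[blk_ids])
  rand_cov <- mean(vapply(1:20, function(i) {
    rr <- setNames(sample(n), g$cells$id)
    mean(priority_mask(rr, 0.30)$protected[blk_ids])
  }, numeric(1)))
  expect_gt(prio_cov, rand_cov)
})

test_that("scenario bundles are byte-reproducible and write plain-text files", {
  spec <- small_scenario()
  b1 <- simulate_scenario(spec, seed = 21)
  b2 <- simulate_scenario(spec, seed = 21)
  expect_identical(write_newick(b1$tree), write_newick(b2$tree))
  expect_identical(as.matrix(b1$grid$presence), as.matrix(b2$grid$presence))
  expect_identical(b1$layers$MAT, b2$layers$MAT)
  expect_identical(b1$protection$priority_rank, b2$protection$priority_rank)

  dir <- withr::local_tempdir()
  write_scenario(b1, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "occurrences.csv",
                                               "layers.csv", "protection.csv",
                                               "scenario.json")))))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, b1$tree$tip.label)
  g2 <- read_occurrences(file.path(dir, "occurrences.csv"), b1$grid$cells)
  expect_equal(as.matrix(g2$presence), as.matrix(b1$grid$presence))
})
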