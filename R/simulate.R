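#' Simulate a birth-death phylogeny conditioned on a tip count
#'
#' Forward-time constant-rate birth-death simulation that stops the moment the
#' number of living lineages first reaches `n_tips`; extinct side branches are
#' pruned, so the returned tree is ultrametric over its `n_tips` extant
#' species; a final grace period (one waiting time at `n_tips` lineages,
#' stopping before the next event) gives the youngest tips positive length.
#' Runs that go extinct before reaching `n_tips` are retried up to
#' `max_retries` times. The stem above the root split is not returned, so
#' under pure birth (death = 0) the crown depth is a sum of independent
#' exponentials `Exp(k * birth)`, k = 2..n, with mean `(H(n) - 1) / birth`
#' (harmonic number), which is what the generator's tests check in closed
#' form.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed optional integer seed.
#' @param max_retries bounded retries after whole-tree extinction.
#' @return an ultrametric `phylo` object with tips `t1..tn`.
#' @export
simulate_phylogeny <- function(n_tips, birth, death = 0, seed = NULL,
                               max_retries = 100) {
  if (n_tips < 2) stopf("`n_tips` must be >= 2")
  if (!(birth > death) || death < 0) stopf("need birth > death >= 0")
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      res <- bd_forward(n_tips, birth, death)
      if (!is.null(res)) {
        res$tip.label <- sprintf("t%d", seq_len(n_tips))
        return(res)
      }
    }
    stopf("failed to reach %d tips in %d attempts (death rate too high?)",
          n_tips, max_retries)
  })
}

# one forward pass; NULL on extinction before reaching n_tips
bd_forward <- function(n_tips, birth, death) {
  # lineage bookkeeping: start time, parent links, children (0 or 2), end time
  n_max <- 4L * n_tips + 8L
  start <- numeric(n_max)
  child1 <- child2 <- integer(n_max)
  endt <- rep(NA_real_, n_max)
  n_lin <- 1L
  alive_set <- 1L
  t <- 0
  while (length(alive_set) < n_tips) {
    k <- length(alive_set)
    if (k == 0L) return(NULL)
    t <- t + stats::rexp(1L, k * (birth + death))
    lin <- alive_set[sample.int(k, 1L)]
    if (stats::runif(1L) < birth / (birth + death)) {
      if (n_lin + 2L > n_max) {  # grow storage
        start <- c(start, numeric(n_max))
        child1 <- c(child1, integer(n_max))
        child2 <- c(child2, integer(n_max))
        endt <- c(endt, rep(NA_real_, n_max))
        n_max <- n_max * 2L
      }
      a <- n_lin + 1L; b <- n_lin + 2L
      n_lin <- b
      start[a] <- start[b] <- t
      child1[lin] <- a; child2[lin] <- b
      endt[lin] <- t
      alive_set <- c(setdiff(alive_set, lin), a, b)
    } else {
      endt[lin] <- t
      alive_set <- setdiff(alive_set, lin)
    }
  }
  # grace period: stop just before the next event so young tips get length
  t <- t + stats::rexp(1L, n_tips * (birth + death))
  endt[alive_set] <- t
  if (child1[1L] == 0L) return(NULL)  # root never split (n_tips >= 2)
  # assemble Newick including extinct tips, then prune them
  nwk <- function(lin) {
    if (child1[lin] == 0L) {
      tag <- if (lin %in% alive_set) sprintf("a%d", lin) else sprintf("x%d", lin)
      sprintf("%s:%.10f", tag, endt[lin] - start[lin])
    } else {
      sprintf("(%s,%s):%.10f", nwk(child1[lin]), nwk(child2[lin]),
              endt[lin] - start[lin])
    }
  }
  txt <- paste0("(", nwk(child1[1L]), ",", nwk(child2[1L]), ");")
  tree <- ape::read.tree(text = txt)
  extinct <- grep("^x", tree$tip.label, value = TRUE)
  if (length(extinct) == length(tree$tip.label)) return(NULL)
  if (length(extinct)) tree <- ape::drop.tip(tree, extinct)
  if (length(tree$tip.label) != n_tips) return(NULL)
  tree
}

# rescale a tree so its maximum root-to-tip depth equals `depth`
rescale_depth <- function(tree, depth) {
  cur <- max(ape::node.depth.edgelength(tree))
  if (cur <= 0) stopf("tree has zero depth")
  tree$edge.length <- tree$edge.length * depth / cur
  tree
}

#' Scenario specification for the synthetic world
#'
#' Collects every knob of the synthetic generator: lattice size, species
#' numbers, diversification rates, planted refugium blocks (with their
#' endemism type), range-size distribution, environmental autocorrelation
#' length and per-layer hotspot offsets (in within-layer standard deviation
#' units), and protection coverage fractions. All stochastic draws downstream
#' derive from one master seed.
#'
#' Blocks are given as `c(row_min, row_max, col_min, col_max)` on the lattice.
#' The default world is a 30 x 30 lattice (900 cells) with 122 species: 88
#' widespread background species, 10 paleo endemics (long isolated branches
#' confined to the paleo block), a 14-species recent radiation of which 12
#' are confined to the neo block (two members stay widespread, so the
#' radiation's stem has a wide range and the block's endemic branch mass is
#' genuinely short), and 10 mixed-block endemics (5 long-branch + 5
#' short-branch species). Offsets reproduce the qualitative hotspot contrasts
#' the pipeline is meant to detect: hotspots sit in milder anomaly
#' (climatically more stable), topographically rougher, wetter/warmer and more
#' human-modified cells, and face larger future anomalies.
#'
#' @param nx,ny lattice dimensions.
#' @param n_background,n_paleo,n_neo,n_mixed species counts per role.
#' @param birth,death diversification rates for the simulated clades.
#' @param neo_depth depth of the recent radiations as a fraction of tree
#'   depth 1.
#' @param paleo_block,neo_block,mixed_block refugium blocks.
#' @param range_meanlog,range_sdlog lognormal range-size parameters
#'   (cells) for background species.
#' @param planted_range_max maximal range size of planted endemics.
#' @param n_clusters background clades share this many range-seed clusters.
#' @param env_corr_length Gaussian-field correlation length (cell units;
#'   correlation falls to 1/e at this distance).
#' @param offsets named list: per-layer `c(mean, hotspot_offset)` in sd units.
#' @param pa_coverage existing protected-area coverage fraction.
#' @param priority_fractions top-priority mask fractions.
#' @param priority_noise sd of the noise added to the priority score.
#' @param min_richness cell filter threshold used downstream.
#' @return object of class `scenario_spec` (a list).
#' @export
scenario_spec <- function(nx = 30, ny = 30,
                          n_background = 88, n_paleo = 10, n_neo = 14,
                          n_mixed = 10,
                          birth = 1, death = 0, neo_depth = 0.05,
                          paleo_block = c(3, 6, 3, 6),
                          neo_block = c(3, 6, nx - 5, nx - 2),
                          mixed_block = c(ny - 6, ny - 3,
                                          floor(nx / 2) - 1,
                                          floor(nx / 2) + 2),
                          range_meanlog = log(0.10 * nx * ny),
                          range_sdlog = 1,
                          planted_range_max = 4,
                          n_clusters = 8,
                          env_corr_length = 3,
                          offsets = NULL,
                          pa_coverage = 0.10,
                          priority_fractions = c(0.17, 0.30, 0.50),
                          priority_noise = 0.5,
                          min_richness = 5) {
  default_offsets <- list(
    MAT              = c(mean = 0,  offset = 0.5),
    AP               = c(mean = 0,  offset = 0.5),
    LGM_MAT_anom     = c(mean = -1, offset = 0.8),
    LGM_AP_anom      = c(mean = -0.5, offset = 0.4),
    Miocene_MAT_anom = c(mean = 1,  offset = -0.8),
    Miocene_AP_anom  = c(mean = 0.5, offset = -0.4),
    elev_range       = c(mean = 0,  offset = 1.0),
    HMI              = c(mean = 0,  offset = 0.8),
    future_MAT_anom  = c(mean = 1,  offset = 0.5),
    future_AP_anom   = c(mean = 0.5, offset = 0.5)
  )
  offsets <- offsets %||% default_offsets
  spec <- list(nx = nx, ny = ny,
               n_background = n_background, n_paleo = n_paleo,
               n_neo = n_neo, n_mixed = n_mixed,
               birth = birth, death = death, neo_depth = neo_depth,
               blocks = list(paleo = paleo_block, neo = neo_block,
                             mixed = mixed_block),
               range_meanlog = range_meanlog, range_sdlog = range_sdlog,
               planted_range_max = planted_range_max,
               n_clusters = n_clusters,
               env_corr_length = env_corr_length,
               offsets = offsets,
               pa_coverage = pa_coverage,
               priority_fractions = priority_fractions,
               priority_noise = priority_noise,
               min_richness = min_richness)
  validate_scenario(spec)
  structure(spec, class = "scenario_spec")
}

validate_scenario <- function(spec) {
  for (nm in names(spec$blocks)) {
    b <- spec$blocks[[nm]]
    if (length(b) != 4L || b[1] > b[2] || b[3] > b[4] ||
        b[1] < 1 || b[2] > spec$ny || b[3] < 1 || b[4] > spec$nx)
      stopf("block '%s' outside the %d x %d lattice", nm, spec$ny, spec$nx)
  }
  fr <- c(spec$pa_coverage, spec$priority_fractions)
  if (any(fr < 0 | fr > 1)) stopf("coverage fractions must be in [0, 1]")
  block_cells <- vapply(spec$blocks, function(b)
    (b[2] - b[1] + 1) * (b[4] - b[3] + 1), numeric(1))
  if (spec$planted_range_max > min(block_cells))
    stopf("planted range size exceeds refugium capacity")
  invisible(spec)
}

# cell index helpers on the row-major lattice used by lattice_cells()
cell_index <- function(row, col, nx) (row - 1L) * nx + col
block_cells <- function(block, nx) {
  g <- expand.grid(col = block[3]:block[4], row = block[1]:block[2])
  cell_index(g$row, g$col, nx)
}

#' Scenario phylogeny with planted branch-length structure
#'
#' Builds the ultrametric tree of depth 1 that the planted refugia require:
#' paleo endemics and the long mixed-block endemics are isolated pendant
#' branches of length 1 attached at the root; neo endemics and the short
#' mixed-block endemics form recent radiations (depth `neo_depth`) on long
#' stems (two radiation members, labelled `neobg`, remain widespread to keep
#' the stem's geographic range wide); background species form a birth-death
#' clade of depth 0.8 on a 0.2 stem. The root is deliberately a polytomy,
#' exercising polytomy support downstream.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed.
#' @return a `phylo` object; tip names encode the planted role
#'   (`bg|neobg|paleo|neo|mixl|mixs`; `neobg` ranges like background).
#' @export
scenario_tree <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(seed, {
    relabel <- function(tree, prefix) {
      tree$tip.label <- sprintf("%s_%02d", prefix, seq_along(tree$tip.label))
      tree
    }
    clade_txt <- function(tree, stem) {
      txt <- ape::write.tree(tree)
      sub(";$", sprintf(":%.10f", stem), txt)
    }
    bg <- rescale_depth(relabel(
      simulate_phylogeny(spec$n_background, spec$birth, spec$death), "bg"), 0.8)
    if (spec$n_neo < 4) stopf("need n_neo >= 4")
    # two radiation members stay widespread (labelled neobg): they dilute the
    # range of the radiation's stem so the block's signal comes from the rare
    # SHORT branches, not from the stem itself
    neo <- rescale_depth(relabel(
      simulate_phylogeny(spec$n_neo, spec$birth, spec$death), "neo"),
      spec$neo_depth)
    wide <- sample(spec$n_neo, 2L)
    neo$tip.label[wide] <- sprintf("neobg_%02d", seq_len(2L))
    n_mixl <- ceiling(spec$n_mixed / 2)
    n_mixs <- spec$n_mixed - n_mixl
    if (n_mixs < 2) stopf("need n_mixed >= 4 (at least 2 short-branch species)")
    mixs <- rescale_depth(relabel(
      simulate_phylogeny(n_mixs, spec$birth, spec$death), "mixs"),
      spec$neo_depth)
    pendants <- c(sprintf("paleo_%02d:1", seq_len(spec$n_paleo)),
                  sprintf("mixl_%02d:1", seq_len(n_mixl)))
    txt <- paste0("(", paste(c(pendants,
                               clade_txt(bg, 0.2),
                               clade_txt(neo, 1 - spec$neo_depth),
                               clade_txt(mixs, 1 - spec$neo_depth)),
                             collapse = ","), ");")
    read_newick(txt)
  })
}

# spreading-dye range growth: a rook-connected set of `size` cells grown from
# `seed_cell`, optionally confined to `within` (a set of cell indices)
spread_dye <- function(seed_cell, size, nx, ny, within = NULL) {
  allowed <- if (is.null(within)) rep(TRUE, nx * ny) else {
    a <- rep(FALSE, nx * ny); a[within] <- TRUE; a
  }
  if (!allowed[seed_cell]) stopf("seed cell outside the allowed region")
  occ <- integer(0)
  occ_flag <- rep(FALSE, nx * ny)
  frontier <- seed_cell
  while (length(occ) < size && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (occ_flag[pick]) next
    occ_flag[pick] <- TRUE
    occ <- c(occ, pick)
    row <- (pick - 1L) %/% nx + 1L
    col <- (pick - 1L) %% nx + 1L
    nb <- c(if (row > 1L) pick - nx, if (row < ny) pick + nx,
            if (col > 1L) pick - 1L, if (col < nx) pick + 1L)
    nb <- nb[allowed[nb] & !occ_flag[nb]]
    frontier <- c(frontier, nb)
  }
  occ
}

#' Simulate spatially cohesive gridded ranges with planted refugia
#'
#' Every species' range is grown by a spreading-dye process (one
#' rook-connected patch). Background species draw heavy-tailed lognormal
#' range sizes and start from clade-clustered seed cells, so related species
#' co-occur regionally. Planted endemics (recognised by their `paleo`, `neo`,
#' `mixl`, `mixs` tip-name prefixes; for unlabelled trees, terminal branch
#' length ranks decide) are confined to their refugium block with ranges of
#' at most `planted_range_max` cells.
#'
#' @param tree the scenario phylogeny.
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed.
#' @return an unfiltered [occurrence_grid()] over the full lattice.
#' @export
simulate_ranges <- function(tree, spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_phylogeny(tree)
  nx <- spec$nx; ny <- spec$ny
  n_cell <- nx * ny
  cells <- lattice_cells(nx, ny)
  roles <- planted_roles(tree, spec)
  with_seed(seed, {
    block_of <- list(paleo = block_cells(spec$blocks$paleo, nx),
                     neo = block_cells(spec$blocks$neo, nx),
                     mixl = block_cells(spec$blocks$mixed, nx),
                     mixs = block_cells(spec$blocks$mixed, nx))
    # clade-clustered seed cells for background ranges
    bg_tips <- names(roles)[roles == "bg"]
    cl <- split(bg_tips, cut(seq_along(bg_tips), spec$n_clusters, labels = FALSE))
    centers <- lapply(seq_along(cl), function(i)
      c(sample.int(ny, 1L), sample.int(nx, 1L)))
    seed_for <- function(tip) {
      ci <- which(vapply(cl, function(v) tip %in% v, logical(1)))[1L]
      ctr <- centers[[ci]]
      row <- pmin(ny, pmax(1L, ctr[1L] + sample(-3L:3L, 1L)))
      col <- pmin(nx, pmax(1L, ctr[2L] + sample(-3L:3L, 1L)))
      cell_index(row, col, nx)
    }
    records <- lapply(names(roles), function(tip) {
      role <- roles[[tip]]
      if (role == "bg") {
        size <- max(1L, min(n_cell,
          as.integer(ceiling(stats::rlnorm(1, spec$range_meanlog,
                                           spec$range_sdlog)))))
        occ <- spread_dye(seed_for(tip), size, nx, ny)
      } else {
        blk <- block_of[[role]]
        size <- sample.int(spec$planted_range_max, 1L)
        occ <- spread_dye(blk[sample.int(length(blk), 1L)], size, nx, ny,
                          within = blk)
      }
      data.frame(species = tip, cell = cells$id[occ])
    })
    build_grid(do.call(rbind, records), cells)
  })
}

# assign a planted role to each tip: by name prefix when the scenario tree
# is used, otherwise by terminal branch length ranking
planted_roles <- function(tree, spec) {
  tips <- tree$tip.label
  pref <- sub("_.*$", "", tips)
  roles <- ifelse(pref %in% c("paleo", "neo", "mixl", "mixs"), pref, "bg")
  if (!any(roles != "bg")) {
    term <- terminal_branch_lengths(tree)
    ord <- order(term, decreasing = TRUE)
    roles <- rep("bg", length(tips))
    n_mixl <- ceiling(spec$n_mixed / 2)
    roles[ord[seq_len(spec$n_paleo)]] <- "paleo"
    roles[ord[spec$n_paleo + seq_len(n_mixl)]] <- "mixl"
    short <- order(term)
    short <- short[!short %in% ord[seq_len(spec$n_paleo + n_mixl)]]
    roles[short[seq_len(spec$n_neo)]] <- "neo"
    roles[short[spec$n_neo + seq_len(spec$n_mixed - n_mixl)]] <- "mixs"
  }
  stats::setNames(roles, tips)
}

#' Terminal branch length per tip
#'
#' @param tree a `phylo` object.
#' @return named numeric vector over tips.
#' @export
terminal_branch_lengths <- function(tree) {
  n_tip <- length(tree$tip.label)
  tip_edges <- match(seq_len(n_tip), tree$edge[, 2L])
  stats::setNames(tree$edge.length[tip_edges], tree$tip.label)
}

#' Simulate spatially autocorrelated environmental layers
#'
#' Each layer is a Gaussian random field built by kernel-smoothing lattice
#' white noise (Gaussian kernel of sd `env_corr_length / 2`, so the field's
#' correlation decays to 1/e at the stated correlation length), standardized
#' to unit variance, then shifted by the layer mean plus the hotspot offset
#' on planted refugium cells. Offsets are therefore directly recoverable as
#' hotspot minus background group-mean differences in sd units.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional integer seed.
#' @return named list of layers (named numeric vectors over all lattice
#'   cells), with the hotspot indicator attached as attribute
#'   `"hotspot_cells"`.
#' @export
simulate_env_layers <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  nx <- spec$nx; ny <- spec$ny
  cells <- lattice_cells(nx, ny)
  xy <- as.matrix(cells[, c("x", "y")])
  s <- spec$env_corr_length / 2
  K <- exp(-as.matrix(stats::dist(xy))^2 / (2 * s^2))
  norm <- sqrt(rowSums(K^2))
  hot <- rep(FALSE, nrow(cells))
  for (b in spec$blocks) hot[block_cells(b, nx)] <- TRUE
  with_seed(seed, {
    layers <- lapply(spec$offsets, function(par) {
      z <- stats::rnorm(nrow(cells))
      field <- as.numeric(K %*% z) / norm
      val <- field + par[["mean"]] + par[["offset"]] * hot
      stats::setNames(val, cells$id)
    })
    names(layers) <- names(spec$offsets)
    attr(layers, "hotspot_cells") <- cells$id[hot]
    layers
  })
}

#' Simulate protection masks and priority rankings
#'
#' The existing-protected-area mask protects a random `pa_coverage` fraction
#' of cells (exact count). The priority ranking scores cells by standardized
#' richness plus a planted-refugium bonus plus noise, so priority masks
#' preferentially cover diversity; the top-fraction masks are nested by
#' construction.
#'
#' @param spec a [scenario_spec()].
#' @param grid the simulated [occurrence_grid()] (richness feeds the
#'   priority score).
#' @param seed optional integer seed.
#' @return list with `existing` ([protection_scheme()]), one scheme per
#'   priority fraction (`top17`, ...), and the `priority_rank` layer.
#' @export
simulate_protection <- function(spec, grid, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(grid, "occurrence_grid"))
  ids <- grid$cells$id
  n <- length(ids)
  rich <- richness(grid)
  hot <- rep(FALSE, n)
  all_cells <- lattice_cells(spec$nx, spec$ny)
  for (b in spec$blocks)
    hot <- hot | ids %in% all_cells$id[block_cells(b, spec$nx)]
  with_seed(seed, {
    n_pa <- as.integer(ceiling(spec$pa_coverage * n))
    pa <- stats::setNames(rep(FALSE, n), ids)
    pa[sample.int(n, n_pa)] <- TRUE
    score <- as.numeric(scale(rich)) + 1.5 * hot +
      stats::rnorm(n, sd = spec$priority_noise)
    prank <- stats::setNames(rank(-score, ties.method = "first"), ids)
    out <- list(existing = protection_scheme(pa, "existing_PA"))
    for (f in spec$priority_fractions)
      out[[sprintf("top%d", round(100 * f))]] <- priority_mask(prank, f)
    out$priority_rank <- prank
    out
  })
}

#' Simulate a complete scenario bundle
#'
#' Runs the four generators off one master seed (stage seeds are drawn from
#' it, so the bundle is byte-reproducible) and returns everything the
#' pipeline consumes.
#'
#' @param spec a [scenario_spec()].
#' @param seed master integer seed.
#' @return list with `spec`, `tree`, `grid` (unfiltered), `layers`,
#'   `protection`, `seeds`.
#' @export
simulate_scenario <- function(spec = scenario_spec(), seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  tree <- scenario_tree(spec, seed = seeds[1L])
  grid <- simulate_ranges(tree, spec, seed = seeds[2L])
  layers <- simulate_env_layers(spec, seed = seeds[3L])
  protection <- simulate_protection(spec, grid, seed = seeds[4L])
  list(spec = spec, tree = tree, grid = grid, layers = layers,
       protection = protection,
       seeds = stats::setNames(seeds, c("tree", "ranges", "layers",
                                        "protection")))
}

#' Write a scenario bundle as plain-text files
#'
#' Writes `tree.nwk`, `occurrences.csv`, `layers.csv`, `protection.csv`, and
#' `scenario.json` (the resolved spec and stage seeds) to a directory.
#'
#' @param bundle a [simulate_scenario()] result.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_occurrences(bundle$grid, file.path(dir, "occurrences.csv"))
  lay <- data.frame(cell_id = names(bundle$layers[[1L]]),
                    do.call(cbind, lapply(bundle$layers, unname)))
  utils::write.csv(lay, file.path(dir, "layers.csv"),
                   row.names = FALSE, quote = FALSE)
  pr <- bundle$protection
  prot <- data.frame(cell_id = names(pr$existing$protected),
                     existing = as.integer(pr$existing$protected))
  for (nm in setdiff(names(pr), c("existing", "priority_rank")))
    prot[[nm]] <- as.integer(pr[[nm]]$protected[prot$cell_id])
  prot$priority_rank <- as.integer(pr$priority_rank[prot$cell_id])
  utils::write.csv(prot, file.path(dir, "protection.csv"),
                   row.names = FALSE, quote = FALSE)
  spec_out <- unclass(bundle$spec)
  spec_out$seeds <- as.list(bundle$seeds)
  jsonlite::write_json(spec_out, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
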