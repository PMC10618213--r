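# Independent brute-force oracles and random-instance generators.
# The PE oracle deliberately avoids the package's sparse-matrix machinery:
# it enumerates descendant tips by walking the edge list and loops over
# branches x cells.

oracle_descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) oracle_descendant_tips(tree, k)))
}

# dense presence matrix (species x cells) in, per-cell PE out
oracle_pe <- function(tree, presence, lengths = tree$edge.length,
                      scaled = FALSE) {
  cells <- colnames(presence)
  pe <- stats::setNames(numeric(length(cells)), cells)
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[oracle_descendant_tips(tree, tree$edge[e, 2])]
    occ <- vapply(cells, function(cl) any(presence[tips, cl] > 0), logical(1))
    r <- sum(occ)
    if (r > 0) pe[occ] <- pe[occ] + lengths[e] / r
  }
  if (scaled) pe <- pe / sum(lengths)
  pe
}

oracle_metrics <- function(tree, presence, scaled = TRUE) {
  n_edge <- nrow(tree$edge)
  len_eq <- rep(sum(tree$edge.length) / n_edge, n_edge)
  pe_o <- oracle_pe(tree, presence, tree$edge.length, scaled)
  pe_e <- oracle_pe(tree, presence, len_eq, scaled)
  list(PE_original = pe_o, PE_equal = pe_e,
       RPE = ifelse(pe_e > 0, pe_o / pe_e, NA_real_))
}

# random tree with uniform branch lengths; random grid where every species
# holds >= 1 cell
random_instance <- function(n_tip = 8, n_cell = 6, p_occ = 0.35) {
  tree <- ape::rtree(n_tip, br = function(n) stats::runif(n, 0.1, 2))
  cells <- data.frame(id = sprintf("c%d", seq_len(n_cell)),
                      x = seq_len(n_cell), y = 0)
  presence <- matrix(0, n_tip, n_cell,
                     dimnames = list(tree$tip.label, cells$id))
  for (i in seq_len(n_tip)) {
    k <- max(1L, stats::rbinom(1, n_cell, p_occ))
    presence[i, sample.int(n_cell, k)] <- 1
  }
  list(tree = tree, presence = presence,
       grid = occurrence_grid(presence, cells))
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# build a canape_classification directly from category counts, for
# worked-example arithmetic on printed cell counts
make_classification <- function(counts, prefix = "cell") {
  cats <- rep(names(counts), unlist(counts))
  df <- data.frame(cell = sprintf("%s%06d", prefix, seq_along(cats)),
                   category = factor(cats, levels = c("neo", "paleo", "mixed",
                                                      "non_significant",
                                                      "excluded")))
  df$hotspot <- df$category %in% c("neo", "paleo", "mixed")
  class(df) <- c("canape_classification", "data.frame")
  df
}

# small scenario used by several suites: fast but with all planted blocks
small_scenario <- function() {
  scenario_spec(nx = 20, ny = 20,
                n_background = 40, n_paleo = 6, n_neo = 8, n_mixed = 6,
                paleo_block = c(3, 6, 3, 6),
                neo_block = c(3, 6, 15, 18),
                mixed_block = c(15, 18, 9, 12),
                n_clusters = 5)
}

# all distinct arrangements of a multiset of labels (exchangeability-reduced
# enumeration of the tip-shuffle null)
multiset_permutations <- function(labels) {
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (u in unique(rest)) rec(c(prefix, u), rest[-match(u, rest)])
  }
  rec(character(0), labels)
  out
}
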