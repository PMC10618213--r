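#' Shuffle the tips of a phylogeny
#'
#' The CANAPE null model: permute which species sits at which tip, leaving the
#' topology and the multiset of branch lengths untouched. Because the
#' occurrence grid is not modified, per-cell species richness and per-species
#' range size are exactly preserved under the null.
#'
#' @param tree a `phylo` object.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return a `phylo` object with permuted tip labels.
#' @export
shuffle_tips <- function(tree, seed = NULL) {
  validate_phylogeny(tree)
  with_seed(seed, {
    tree$tip.label <- sample(tree$tip.label)
    tree
  })
}

#' Tip-shuffling randomization test for the endemism metrics
#'
#' Recomputes PE on the original tree, PE on the equal-branch comparison tree,
#' and RPE under `n_iter` independent tip shuffles, and counts, per cell and
#' per metric, how many null draws fall strictly above (and tie with) the
#' observed value. One-tailed rates use the +1 permutation correction:
#' `p_high = (1 + #\{null >= obs\}) / (n_iter + 1)` and symmetrically for
#' `p_low`, so ties count against significance.
#'
#' The branch-incidence machinery is keyed to the topology once; each
#' iteration only re-aggregates the incidence under a permuted species-to-tip
#' assignment, which is algebraically identical to recomputing the metrics on
#' a tip-shuffled tree.
#'
#' @param tree a `phylo` object.
#' @param grid a filtered [occurrence_grid()] containing all tips.
#' @param n_iter number of randomization iterations (the reference analysis
#'   uses 999).
#' @param seed optional integer seed.
#' @param scaled passed to the PE computation (does not affect ranks).
#' @return object of class `pe_randomization`: list with `n_iter`, `cells`,
#'   and per-metric data.frames (`PE_original`, `PE_equal`, `RPE`) holding
#'   `observed`, `count_greater`, `count_equal`, `p_high`, `p_low`.
#' @export
randomization_test <- function(tree, grid, n_iter = 999, seed = NULL,
                               scaled = TRUE) {
  validate_phylogeny(tree)
  stopifnot(inherits(grid, "occurrence_grid"))
  if (n_iter < 1) stopf("`n_iter` must be >= 1")
  missing <- setdiff(tree$tip.label, rownames(grid$presence))
  if (length(missing))
    stopf("tip(s) absent from grid: %s",
          paste(utils::head(missing, 5L), collapse = ", "))

  D <- edge_tip_matrix(tree)
  P <- grid$presence[tree$tip.label, , drop = FALSE]
  total <- sum(tree$edge.length)
  if (scaled && total <= 0) stopf("total tree length is zero; cannot scale PE")
  len_eq <- rep(total / nrow(tree$edge), nrow(tree$edge))
  scale_div <- if (scaled) total else 1

  observe <- function(Pm) {
    inc <- (D %*% Pm) > 0
    pe_o <- pe_from_incidence(inc, tree$edge.length) / scale_div
    pe_e <- pe_from_incidence(inc, len_eq) / scale_div
    list(PE_original = pe_o, PE_equal = pe_e,
         RPE = ifelse(pe_e > 0, pe_o / pe_e, NA_real_))
  }
  obs <- observe(P)
  n_cell <- ncol(P)
  metrics <- c("PE_original", "PE_equal", "RPE")
  gt <- eq <- sapply(metrics, function(m) numeric(n_cell), simplify = FALSE)
  n_tip <- nrow(P)
  tol <- 1e-12

  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      perm <- sample.int(n_tip)
      null <- observe(P[perm, , drop = FALSE])
      for (m in metrics) {
        d <- null[[m]] - obs[[m]]
        gt[[m]] <- gt[[m]] + as.numeric(!is.na(d) & d > tol)
        eq[[m]] <- eq[[m]] + as.numeric(!is.na(d) & abs(d) <= tol)
      }
    }
  })

  tabs <- lapply(metrics, function(m) {
    cg <- gt[[m]]; ce <- eq[[m]]
    # NA metrics (RPE undefined) never accumulate; mark their rates NA
    undef <- is.na(obs[[m]])
    data.frame(cell = colnames(P),
               observed = obs[[m]],
               count_greater = ifelse(undef, NA, cg),
               count_equal = ifelse(undef, NA, ce),
               p_high = ifelse(undef, NA, (1 + cg + ce) / (n_iter + 1)),
               p_low = ifelse(undef, NA, (1 + (n_iter - cg)) / (n_iter + 1)))
  })
  names(tabs) <- metrics
  structure(c(list(n_iter = n_iter, cells = colnames(P)), tabs),
            class = "pe_randomization")
}

#' @export
print.pe_randomization <- function(x, ...) {
  cat(sprintf("<pe_randomization> %d cells, %d iterations\n",
              length(x$cells), x$n_iter))
  invisible(x)
}

#' CANAPE classification of grid cells
#'
#' Two-step categorical analysis of neo- and paleo-endemism. Step 1 (the
#' gate): a cell is an endemism candidate if PE on the original tree or PE on
#' the comparison tree is significantly high (one-tailed at `alpha/2`, i.e.
#' above the 97.5% null quantile for `alpha = 0.05`). Step 2, among
#' candidates: significantly high RPE marks paleo-endemism (concentration of
#' rare long branches), significantly low RPE marks neo-endemism (rare short
#' branches), and candidates without a dominant RPE tail are mixed. Cells
#' failing the gate are non-significant.
#'
#' @param rand a [randomization_test()] result.
#' @param alpha two-tailed significance level (each tail uses `alpha/2`).
#' @param strict_both_pe if `TRUE`, the mixed category additionally requires
#'   both PE metrics significantly high; gate-passing cells that qualify on
#'   one metric only and have a non-significant RPE fall back to
#'   non-significant. The default (`FALSE`) labels every gate-passing cell
#'   without an RPE verdict as mixed.
#' @param all_cells optional full cell universe; cells absent from `rand`
#'   (e.g. dropped by the richness filter) are reported as `excluded`.
#' @return object of class `canape_classification`: data.frame with columns
#'   `cell`, `category` (factor: neo, paleo, mixed, non_significant,
#'   excluded), `hotspot` (logical).
#' @export
canape_classify <- function(rand, alpha = 0.05, strict_both_pe = FALSE,
                            all_cells = NULL) {
  stopifnot(inherits(rand, "pe_randomization"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be in (0, 1)")
  thr <- alpha / 2
  hi <- function(tab) !is.na(tab$p_high) & tab$p_high <= thr
  lo <- function(tab) !is.na(tab$p_low) & tab$p_low <= thr

  pe_hi <- hi(rand$PE_original)
  eq_hi <- hi(rand$PE_equal)
  rpe_hi <- hi(rand$RPE)
  rpe_lo <- lo(rand$RPE)

  gate <- pe_hi | eq_hi
  category <- rep("non_significant", length(gate))
  category[gate & rpe_hi] <- "paleo"
  category[gate & rpe_lo] <- "neo"
  mixed <- gate & !rpe_hi & !rpe_lo
  if (strict_both_pe) {
    category[mixed & pe_hi & eq_hi] <- "mixed"
  } else {
    category[mixed] <- "mixed"
  }

  out <- data.frame(cell = rand$cells, category = category)
  if (!is.null(all_cells)) {
    extra <- setdiff(as.character(all_cells), rand$cells)
    if (length(extra))
      out <- rbind(out, data.frame(cell = extra, category = "excluded"))
  }
  out$category <- factor(out$category,
                         levels = c("neo", "paleo", "mixed",
                                    "non_significant", "excluded"))
  out$hotspot <- out$category %in% c("neo", "paleo", "mixed")
  class(out) <- c("canape_classification", "data.frame")
  out
}

#' Hotspot flag per cell
#'
#' A hotspot is any cell classified as a centre of neo-, paleo-, or mixed
#' endemism; non-significant and excluded cells are non-hotspots.
#'
#' @param classification a [canape_classify()] result.
#' @return named logical vector over cells.
#' @export
group_hotspots <- function(classification) {
  stopifnot(inherits(classification, "canape_classification"))
  stats::setNames(classification$category %in% c("neo", "paleo", "mixed"),
                  classification$cell)
}

#' Per-category counts and percentages
#'
#' Percentages are relative to the analysed cells (excluded cells are not in
#' the denominator) and reported rounded half away from zero to one decimal;
#' the raw fractions are kept alongside.
#'
#' @param classification a [canape_classify()] result.
#' @return data.frame with columns `category`, `count`, `fraction`,
#'   `percentage`, plus a `hotspot` summary row set (`hotspot`,
#'   `non_hotspot`).
#' @export
category_percentages <- function(classification) {
  stopifnot(inherits(classification, "canape_classification"))
  analysed <- classification[classification$category != "excluded", ]
  n <- nrow(analysed)
  if (n == 0L) stopf("no analysed cells to summarise")
  cats <- c("neo", "paleo", "mixed", "non_significant")
  counts <- vapply(cats, function(k) sum(analysed$category == k), integer(1))
  counts <- c(counts,
              hotspot = sum(analysed$hotspot),
              non_hotspot = sum(!analysed$hotspot))
  frac <- counts / n
  data.frame(category = names(counts),
             count = as.integer(counts),
             n_analysed = n,
             fraction = as.numeric(frac),
             percentage = round_half_up(100 * frac, 1),
             row.names = NULL)
}

#' Overlap of hotspot sets between two classifications
#'
#' Compares hotspot cells of two analyses (e.g. two taxonomic groups run on
#' the same grid) over the intersection of their analysed cell universes:
#' counts of A-only, B-only and shared hotspot cells, the percentage of each
#' group's hotspots that are shared, and the union-hotspot percentage over all
#' analysed cells.
#'
#' @param class_a,class_b [canape_classify()] results.
#' @param labels length-2 character, names for the two groups.
#' @return object of class `overlap_summary` (a list).
#' @export
overlap_summary <- function(class_a, class_b, labels = c("A", "B")) {
  stopifnot(inherits(class_a, "canape_classification"),
            inherits(class_b, "canape_classification"))
  universe <- intersect(class_a$cell[class_a$category != "excluded"],
                        class_b$cell[class_b$category != "excluded"])
  if (length(universe) == 0L)
    stopf("the analysed cell universes of the two classifications do not intersect")
  hot_a <- intersect(class_a$cell[class_a$hotspot], universe)
  hot_b <- intersect(class_b$cell[class_b$hotspot], universe)
  shared <- intersect(hot_a, hot_b)
  un <- union(hot_a, hot_b)
  structure(list(
    labels = labels,
    n_analysed = length(universe),
    n_a = length(hot_a),
    n_b = length(hot_b),
    n_shared = length(shared),
    n_a_only = length(hot_a) - length(shared),
    n_b_only = length(hot_b) - length(shared),
    n_union = length(un),
    pct_shared_of_a = report_percentage(length(shared), max(length(hot_a), 1L)),
    pct_shared_of_b = report_percentage(length(shared), max(length(hot_b), 1L)),
    pct_union_of_analysed = report_percentage(length(un), length(universe)),
    a_only = setdiff(hot_a, shared),
    b_only = setdiff(hot_b, shared),
    shared = shared
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %s: %d hotspots, %s: %d hotspots\n",
              x$labels[1], x$n_a, x$labels[2], x$n_b))
  cat(sprintf("  shared %d (%.1f%% of %s, %.1f%% of %s); union %d of %d analysed (%.1f%%)\n",
              x$n_shared, x$pct_shared_of_a, x$labels[1],
              x$pct_shared_of_b, x$labels[2],
              x$n_union, x$n_analysed, x$pct_union_of_analysed))
  invisible(x)
}

#' Write a CANAPE classification as CSV
#'
#' @param classification a [canape_classify()] result.
#' @param path output CSV path.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "canape_classification"))
  utils::write.csv(as.data.frame(classification), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
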