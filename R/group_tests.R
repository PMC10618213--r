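# Enumerate all assignments of `sizes` group labels to n observations,
# calling fun(index_list) for each distinct partition. Used for exact
# Fisher-Pitman p-values on small samples.
enumerate_partitions <- function(n, sizes, fun) {
  # recursive choice of index sets; the last group takes the remainder
  rec <- function(avail, sizes_left, acc) {
    if (length(sizes_left) == 1L) {
      fun(c(acc, list(avail)))
      return(invisible(NULL))
    }
    sets <- utils::combn(avail, sizes_left[1L], simplify = FALSE)
    for (s in sets) rec(setdiff(avail, s), sizes_left[-1L], c(acc, list(s)))
    invisible(NULL)
  }
  rec(seq_len(n), sizes, list())
}

n_partitions <- function(sizes) {
  n <- sum(sizes)
  out <- 1
  for (s in sizes[-length(sizes)]) {
    out <- out * choose(n, s)
    n <- n - s
  }
  out
}

#' Two-sample Fisher-Pitman permutation test
#'
#' Permutation test on the raw values: the statistic is the sum of the first
#' sample (equivalent to its mean at fixed group sizes), and the p-value is
#' the proportion of relabellings with a statistic as or more extreme. All
#' `choose(n, n_x)` partitions are enumerated exactly when their number does
#' not exceed `exact_cap`; otherwise a Monte-Carlo sample of `n_perm`
#' relabellings is used with the +1 correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param n_perm Monte-Carlo permutations when exact enumeration is off.
#' @param seed optional seed for the Monte-Carlo path.
#' @param alternative "two.sided" (extremeness as |sum - E sum|), "greater",
#'   or "less" (tail of the first sample's sum).
#' @param exact_cap enumerate exactly when `choose(n, n_x) <= exact_cap`.
#' @return list with `statistic` (sum of `x`), `p_value`, `method`
#'   ("exact" or "monte_carlo"), `n_used`.
#' @export
fisher_pitman_two_sample <- function(x, y, n_perm = 10000, seed = NULL,
                                     alternative = "two.sided",
                                     exact_cap = 20000) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  S_obs <- sum(x)
  E <- nx * mean(pooled)
  tol <- 1e-9 * max(1, abs(S_obs), abs(E))
  extreme <- switch(alternative,
    two.sided = function(S) abs(S - E) >= abs(S_obs - E) - tol,
    greater = function(S) S >= S_obs - tol,
    less = function(S) S <= S_obs + tol,
    stopf("unknown alternative '%s'", alternative))
  if (choose(n, nx) <= exact_cap) {
    count <- 0L; total <- 0L
    enumerate_partitions(n, c(nx, n - nx), function(idx) {
      S <- sum(pooled[idx[[1L]]])
      if (extreme(S)) count <<- count + 1L
      total <<- total + 1L
    })
    return(list(statistic = S_obs, p_value = count / total,
                method = "exact", n_used = total))
  }
  stats_mc <- with_seed(seed,
    vapply(seq_len(n_perm),
           function(i) sum(pooled[sample.int(n, nx)]), numeric(1)))
  p <- (1 + sum(extreme(stats_mc))) / (n_perm + 1)
  list(statistic = S_obs, p_value = p, method = "monte_carlo", n_used = n_perm)
}

# between-group sum of squares of means, the k-sample Fisher-Pitman statistic
k_sample_statistic <- function(values, group_idx, grand_mean) {
  s <- 0
  for (idx in group_idx) {
    m <- mean(values[idx])
    s <- s + length(idx) * (m - grand_mean)^2
  }
  s
}

#' K-sample Fisher-Pitman permutation test
#'
#' Generalizes the two-sample test to k groups with the between-group
#' sum-of-squares statistic sum_g n_g (mean_g - grand mean)^2; large values
#' indicate group separation, and the permutation p-value is the upper-tail
#' proportion over relabellings. Exact enumeration is used when the number of
#' distinct partitions is within `exact_cap`.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 non-empty groups).
#' @param n_perm Monte-Carlo permutations.
#' @param seed optional seed.
#' @param exact_cap exact-enumeration threshold on the partition count.
#' @return list with `statistic`, `p_value`, `method`, `n_used`,
#'   `group_sizes`.
#' @export
fisher_pitman_k_sample <- function(values, groups, n_perm = 10000,
                                   seed = NULL, exact_cap = 20000) {
  values <- as.numeric(values)
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stopf("length mismatch")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least 2 groups")
  if (any(sizes == 0L)) stopf("empty group(s): %s",
                              paste(names(sizes)[sizes == 0], collapse = ", "))
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  n <- length(values)
  gm <- mean(values)
  obs_idx <- split(seq_len(n), groups)
  S_obs <- k_sample_statistic(values, obs_idx, gm)
  tol <- 1e-9 * max(1, S_obs)
  sizes_int <- as.integer(sizes)
  if (n_partitions(sizes_int) <= exact_cap) {
    count <- 0L; total <- 0L
    enumerate_partitions(n, sizes_int, function(idx) {
      if (k_sample_statistic(values, idx, gm) >= S_obs - tol)
        count <<- count + 1L
      total <<- total + 1L
    })
    return(list(statistic = S_obs, p_value = count / total,
                method = "exact", n_used = total,
                group_sizes = sizes_int))
  }
  ends <- cumsum(sizes_int)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  stats_mc <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sh <- sample.int(n)
    idx <- lapply(seq_along(sizes_int),
                  function(g) sh[starts[g]:ends[g]])
    k_sample_statistic(values, idx, gm)
  }, numeric(1)))
  p <- (1 + sum(stats_mc >= S_obs - tol)) / (n_perm + 1)
  list(statistic = S_obs, p_value = p, method = "monte_carlo",
       n_used = n_perm, group_sizes = sizes_int)
}

# standardized two-sample sum statistic under sampling without replacement
pair_zstat <- function(vals, is_g) {
  N <- length(vals); ng <- sum(is_g)
  S <- sum(vals[is_g])
  mu <- ng * mean(vals)
  sig2 <- ng * (N - ng) / (N - 1) * (sum((vals - mean(vals))^2) / N)
  if (sig2 <= 0) return(0)
  (S - mu) / sqrt(sig2)
}

#' Pairwise post-hoc permutation comparisons with multiplicity adjustment
#'
#' After a significant k-sample test, compares every pair of groups with the
#' two-sample Fisher-Pitman statistic. The default adjustment is single-step
#' max-T (Westfall-Young): the full label vector is permuted jointly and each
#' pair's standardized statistic is referred to the permutation distribution
#' of the maximum across pairs, which controls the family-wise error while
#' respecting the dependence between comparisons. `adjust = "holm"` applies
#' the deterministic Holm step-down to the raw pairwise p-values instead.
#' Groups are then summarised by a compact letter display: groups sharing a
#' letter are not significantly different at `alpha`.
#'
#' @param values numeric observations.
#' @param groups group label per observation (k >= 3 groups).
#' @param n_perm permutations for the joint null.
#' @param seed optional seed.
#' @param adjust "maxT" or "holm".
#' @param alpha level for the letter display.
#' @return list with `pairs` (data.frame of raw and adjusted p-values),
#'   `letters` (named character per group), `method`.
#' @export
posthoc_pairwise <- function(values, groups, n_perm = 10000, seed = NULL,
                             adjust = c("maxT", "holm"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  values <- as.numeric(values)
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) < 3L)
    stopf("need k >= 3 groups; use fisher_pitman_two_sample() for two")
  if (any(table(groups) == 0L)) stopf("empty group(s)")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  n <- length(values)

  z_for_labels <- function(lab) {
    vapply(pairs, function(pr) {
      sel <- lab %in% pr
      pair_zstat(values[sel], lab[sel] == pr[1L])
    }, numeric(1))
  }
  z_obs <- z_for_labels(groups)

  perm_z <- with_seed(seed, {
    m <- matrix(0, nrow = n_perm, ncol = length(pairs))
    for (b in seq_len(n_perm)) m[b, ] <- z_for_labels(groups[sample.int(n)])
    m
  })
  p_raw <- vapply(seq_along(pairs), function(j)
    (1 + sum(abs(perm_z[, j]) >= abs(z_obs[j]) - 1e-12)) / (n_perm + 1),
    numeric(1))
  if (adjust == "maxT") {
    maxz <- apply(abs(perm_z), 1L, max)
    p_adj <- vapply(seq_along(pairs), function(j)
      (1 + sum(maxz >= abs(z_obs[j]) - 1e-12)) / (n_perm + 1), numeric(1))
    p_adj <- pmax(p_adj, p_raw)  # single-step never below raw
  } else {
    p_adj <- stats::p.adjust(p_raw, method = "holm")
  }
  tab <- data.frame(group1 = vapply(pairs, `[`, "", 1L),
                    group2 = vapply(pairs, `[`, "", 2L),
                    z = z_obs, p_raw = p_raw, p_adjusted = p_adj)
  list(pairs = tab,
       letters = letter_display(tab, lev, alpha),
       method = adjust)
}

# compact letter display: letters label the maximal cliques of the
# "not significantly different" graph
letter_display <- function(pair_tab, lev, alpha = 0.05) {
  ns <- pair_tab[pair_tab$p_adjusted > alpha, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(lev), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = lev)
  if (nrow(ns))
    g <- igraph::add_edges(g, rbind(match(ns$group1, lev),
                                    match(ns$group2, lev)))
  cliques <- igraph::max_cliques(g)
  # order cliques by their first group to get stable letter assignment
  firsts <- vapply(cliques, function(cl) min(as.integer(cl)), integer(1))
  cliques <- cliques[order(firsts)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(cliques)) {
    members <- lev[as.integer(cliques[[ci]])]
    out[members] <- paste0(out[members], letters[ci])
  }
  out
}
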