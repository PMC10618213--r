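#' Read a rooted Newick phylogeny
#'
#' Wraps `ape::read.tree()` with the validation the endemism metrics rely on:
#' a single root, unique tip labels, branch lengths present and non-negative.
#' Polytomies are permitted. A stem (root) edge, if present in the file, is
#' ignored by all metrics: the root branch has the full species set as
#' descendants and no defined complement.
#'
#' @param x a Newick string or a path to a Newick file.
#' @return a `phylo` object.
#' @export
read_newick <- function(x) {
  is_file <- length(x) == 1L && !grepl("\\(", x) && file.exists(x)
  tree <- tryCatch(
    if (is_file) ape::read.tree(file = x) else ape::read.tree(text = x),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stopf("failed to parse Newick input%s",
          if (is_file) sprintf(" from '%s'", x) else "")
  validate_phylogeny(tree)
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_phylogeny(tree)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylogeny")
  if (is.null(tree$edge.length))
    stopf("phylogeny has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stopf("branch lengths must be non-negative and non-missing")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stopf("duplicate tip label(s): %s", paste(unique(dup), collapse = ", "))
  invisible(tree)
}

# Edge x tip descendant indicator (sparse): entry (e, t) = 1 when tip t
# descends from edge e. Columns follow tree tip order.
edge_tip_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  # accumulate tip sets bottom-up over a postorder edge ordering
  post <- ape::postorder(tree)
  desc <- vector("list", n_tip + tree$Nnode)
  for (t in seq_len(n_tip)) desc[[t]] <- t
  ei <- integer(0); ti <- integer(0)
  for (e in post) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= n_tip) child else desc[[child]]
    parent <- tree$edge[e, 1L]
    desc[[parent]] <- c(desc[[parent]], tips)
    ei <- c(ei, rep.int(e, length(tips)))
    ti <- c(ti, tips)
  }
  Matrix::sparseMatrix(i = ei, j = ti, x = 1, dims = c(n_edge, n_tip),
                       dimnames = list(NULL, tree$tip.label))
}

#' Geographic range of every branch
#'
#' For each non-root branch, the set (and count) of grid cells where at least
#' one descendant tip occurs. A tip branch's range equals that species' range;
#' an internal branch's range is the union of its children's ranges.
#'
#' @param tree a `phylo` object whose tips are all present in `grid`.
#' @param grid an [occurrence_grid()].
#' @return data.frame with one row per edge (in `tree$edge` order): `edge`,
#'   `length`, `range_size`, and a list-column `cells` of occupied cell ids.
#' @export
branch_ranges <- function(tree, grid) {
  validate_phylogeny(tree)
  stopifnot(inherits(grid, "occurrence_grid"))
  missing <- setdiff(tree$tip.label, rownames(grid$presence))
  if (length(missing))
    stopf("tip(s) absent from grid: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  D <- edge_tip_matrix(tree)
  P <- grid$presence[tree$tip.label, , drop = FALSE]
  inc <- (D %*% P) > 0  # edges x cells
  counts <- Matrix::rowSums(inc)
  cell_ids <- colnames(grid$presence)
  trip <- methods::as(inc, "TsparseMatrix")
  cells <- split(cell_ids[trip@j + 1L], factor(trip@i + 1L, levels = seq_len(nrow(inc))))
  data.frame(edge = seq_len(nrow(tree$edge)),
             length = tree$edge.length,
             range_size = as.integer(counts),
             cells = I(unname(cells)))
}

# Shared computational core: per-cell PE for one weight vector per edge.
# inc is the logical edges x cells incidence; w_e = L_e / R_e.
pe_from_incidence <- function(inc, lengths) {
  r <- Matrix::rowSums(inc)
  w <- ifelse(r > 0, lengths / r, 0)
  as.numeric(Matrix::crossprod(inc, w))
}

#' Phylogenetic endemism per grid cell
#'
#' PE of a cell is the sum, over every branch with at least one descendant tip
#' present in the cell, of the branch length divided by the branch's global
#' range size (number of cells occupied by its descendant clade). With
#' `scaled = TRUE` the result is divided by the total tree length, so PE is the
#' proportion of the tree's evolutionary history endemic to the cell.
#'
#' @param tree a `phylo` object.
#' @param grid a filtered [occurrence_grid()] whose species include all tips.
#' @param scaled divide by total tree length?
#' @return named numeric vector of per-cell PE.
#' @export
phylogenetic_endemism <- function(tree, grid, scaled = TRUE) {
  validate_phylogeny(tree)
  stopifnot(inherits(grid, "occurrence_grid"))
  missing <- setdiff(tree$tip.label, rownames(grid$presence))
  if (length(missing))
    stopf("tip(s) absent from grid: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  D <- edge_tip_matrix(tree)
  P <- grid$presence[tree$tip.label, , drop = FALSE]
  inc <- (D %*% P) > 0
  pe <- pe_from_incidence(inc, tree$edge.length)
  if (scaled) {
    total <- sum(tree$edge.length)
    if (total <= 0) stopf("total tree length is zero; cannot scale PE")
    pe <- pe / total
  }
  stats::setNames(pe, colnames(grid$presence))
}

#' Equal-branch-length comparison phylogeny
#'
#' Returns a tree with identical topology and labels in which every non-root
#' branch has length (total original length) / (number of branches). Total
#' tree length is preserved, so PE on the original and comparison trees share
#' a scale and their ratio (RPE) is a pure shape contrast: it asks where the
#' endemic branch length is concentrated on long (old) versus short (young)
#' branches, not how much there is.
#'
#' @param tree a `phylo` object.
#' @return a `phylo` object.
#' @export
equalize_branch_lengths <- function(tree) {
  validate_phylogeny(tree)
  n_edge <- nrow(tree$edge)
  if (n_edge < 1L) stopf("tree has no branches")
  tree$edge.length <- rep(sum(tree$edge.length) / n_edge, n_edge)
  tree
}

#' Relative phylogenetic endemism
#'
#' RPE(cell) = PE_original(cell) / PE_equal(cell), where PE_equal is PE
#' computed on the equal-branch-length comparison tree. Cells where the
#' comparison PE is zero are returned as `NA` (RPE undefined there).
#'
#' @param pe_original named per-cell PE on the original tree.
#' @param pe_equal named per-cell PE on the comparison tree, same cells and
#'   same scaling flag.
#' @return named numeric vector of per-cell RPE.
#' @export
relative_phylogenetic_endemism <- function(pe_original, pe_equal) {
  if (!identical(names(pe_original), names(pe_equal)))
    stopf("cell sets of the two PE vectors differ")
  out <- ifelse(pe_equal > 0, pe_original / pe_equal, NA_real_)
  stats::setNames(out, names(pe_original))
}

#' All three endemism metrics at once
#'
#' Computes PE on the original tree, PE on the equal-branch comparison tree,
#' and their ratio RPE, sharing one branch-incidence pass.
#'
#' @inheritParams phylogenetic_endemism
#' @return data.frame with columns `cell`, `PE_original`, `PE_equal`, `RPE`.
#' @export
endemism_metrics <- function(tree, grid, scaled = TRUE) {
  validate_phylogeny(tree)
  stopifnot(inherits(grid, "occurrence_grid"))
  missing <- setdiff(tree$tip.label, rownames(grid$presence))
  if (length(missing))
    stopf("tip(s) absent from grid: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  D <- edge_tip_matrix(tree)
  P <- grid$presence[tree$tip.label, , drop = FALSE]
  inc <- (D %*% P) > 0
  total <- sum(tree$edge.length)
  if (scaled && total <= 0) stopf("total tree length is zero; cannot scale PE")
  len_eq <- rep(total / nrow(tree$edge), nrow(tree$edge))
  pe_o <- pe_from_incidence(inc, tree$edge.length)
  pe_e <- pe_from_incidence(inc, len_eq)
  if (scaled) {
    pe_o <- pe_o / total
    pe_e <- pe_e / total
  }
  data.frame(cell = colnames(grid$presence),
             PE_original = pe_o,
             PE_equal = pe_e,
             RPE = ifelse(pe_e > 0, pe_o / pe_e, NA_real_))
}

#' Write per-cell endemism metrics as CSV
#'
#' @param metrics data.frame from [endemism_metrics()].
#' @param path output CSV path.
#' @export
write_endemism <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
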