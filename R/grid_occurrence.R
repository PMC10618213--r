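#' Construct an occurrence grid
#'
#' An `occurrence_grid` holds a binary species-by-cell incidence matrix over an
#' indexed set of grid cells with planar centre coordinates. Cell ids are
#' opaque: any equal-area projection (or the synthetic square lattice) is the
#' caller's responsibility, which keeps every downstream metric
#' resolution-agnostic.
#'
#' @param presence binary species x cell matrix (dense or `Matrix` sparse) with
#'   species rownames and cell-id colnames.
#' @param cells data.frame with columns `id`, `x`, `y` (planar centre
#'   coordinates); row order defines cell order and must match `presence`
#'   columns.
#' @return an object of class `occurrence_grid` with elements `presence`
#'   (sparse `dgCMatrix`) and `cells`.
#' @export
occurrence_grid <- function(presence, cells) {
  if (!is.data.frame(cells) || !all(c("id", "x", "y") %in% names(cells)))
    stopf("`cells` must be a data.frame with columns id, x, y")
  cells$id <- as.character(cells$id)
  if (anyDuplicated(cells$id)) stopf("cell ids must be unique")
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stopf("cell coordinates must be finite")
  presence <- methods::as(methods::as(Matrix::Matrix(presence, sparse = TRUE),
                                      "dMatrix"), "CsparseMatrix")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stopf("`presence` needs species rownames and cell colnames")
  if (!identical(colnames(presence), cells$id))
    stopf("`presence` columns must match `cells$id` in order")
  if (anyDuplicated(rownames(presence))) stopf("species labels must be unique")
  v <- presence@x
  if (length(v) && !all(v %in% c(0, 1)))
    stopf("presence entries must be 0 or 1")
  presence <- Matrix::drop0(presence)
  structure(list(presence = presence, cells = cells),
            class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat(sprintf("<occurrence_grid> %d species x %d cells, %d presences\n",
              nrow(x$presence), ncol(x$presence),
              as.integer(sum(x$presence))))
  invisible(x)
}

#' Build an occurrence grid from long-format records
#'
#' Duplicate (species, cell) records collapse to a single presence.
#'
#' @param records data.frame with columns `species` and `cell` (or `cell_id`).
#' @param cells data.frame of grid cells (`id`, `x`, `y`).
#' @return [occurrence_grid()].
#' @export
build_grid <- function(records, cells) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L)
    stopf("no occurrence records supplied")
  records <- as.data.frame(records)
  if ("cell_id" %in% names(records) && !"cell" %in% names(records))
    names(records)[names(records) == "cell_id"] <- "cell"
  if (!all(c("species", "cell") %in% names(records)))
    stopf("`records` must have columns species and cell")
  cells$id <- as.character(cells$id)
  records$species <- as.character(records$species)
  records$cell <- as.character(records$cell)
  unknown <- setdiff(records$cell, cells$id)
  if (length(unknown))
    stopf("unknown cell id(s) in records: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  sp <- sort(unique(records$species))
  i <- match(records$species, sp)
  j <- match(records$cell, cells$id)
  presence <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(sp), nrow(cells)),
    dimnames = list(sp, cells$id)
  )
  presence@x[] <- 1  # collapse duplicates summed by sparseMatrix
  occurrence_grid(presence, cells)
}

#' Per-cell species richness
#'
#' @param grid an [occurrence_grid()].
#' @return named integer vector over cells.
#' @export
richness <- function(grid) {
  stopifnot(inherits(grid, "occurrence_grid"))
  r <- Matrix::colSums(grid$presence)
  stats::setNames(as.integer(r), colnames(grid$presence))
}

#' Per-species range size (number of occupied cells)
#'
#' @param grid an [occurrence_grid()].
#' @return named integer vector over species.
#' @export
range_sizes <- function(grid) {
  stopifnot(inherits(grid, "occurrence_grid"))
  r <- Matrix::rowSums(grid$presence)
  stats::setNames(as.integer(r), rownames(grid$presence))
}

#' Drop species-poor cells
#'
#' Removes cells holding fewer than `min_species` species (low-species cells
#' carry unstable endemism estimates), then drops species whose whole range
#' fell in the removed cells. The default threshold of 5 follows standard
#' practice for 1-degree-scale analyses.
#'
#' @param grid an [occurrence_grid()].
#' @param min_species minimum per-cell richness to retain a cell (>= 1).
#' @return filtered [occurrence_grid()]. Dropped species are reported via a
#'   warning and recorded in the `dropped_species` attribute.
#' @export
filter_min_richness <- function(grid, min_species = 5) {
  stopifnot(inherits(grid, "occurrence_grid"))
  if (min_species < 1) stopf("`min_species` must be >= 1")
  keep_cells <- richness(grid) >= min_species
  if (!any(keep_cells))
    stopf("no cells left: all %d cells have richness < %d",
          ncol(grid$presence), min_species)
  presence <- grid$presence[, keep_cells, drop = FALSE]
  keep_sp <- Matrix::rowSums(presence) > 0
  dropped <- rownames(presence)[!keep_sp]
  if (length(dropped))
    warning(sprintf("%d species lost all cells after filtering and were dropped",
                    length(dropped)), call. = FALSE)
  out <- occurrence_grid(presence[keep_sp, , drop = FALSE],
                         grid$cells[keep_cells, , drop = FALSE])
  attr(out, "dropped_species") <- dropped
  out
}

#' Intersect a phylogeny and a grid on their shared species
#'
#' Tips absent from the grid and species absent from the tree are removed with
#' a warning, mirroring the usual pruning of a megatree to the taxa that have
#' distribution data.
#'
#' @param tree a `phylo` object.
#' @param grid an [occurrence_grid()].
#' @return list with elements `tree` and `grid` restricted to shared species.
#' @export
align_tree_grid <- function(tree, grid) {
  stopifnot(inherits(tree, "phylo"), inherits(grid, "occurrence_grid"))
  shared <- intersect(tree$tip.label, rownames(grid$presence))
  if (length(shared) < 2L)
    stopf("fewer than two species shared between tree and grid")
  n_tip_only <- length(setdiff(tree$tip.label, shared))
  n_grid_only <- length(setdiff(rownames(grid$presence), shared))
  if (n_tip_only || n_grid_only)
    warning(sprintf(
      "intersecting tree and grid: dropped %d tip(s) without occurrences, %d species not in tree",
      n_tip_only, n_grid_only), call. = FALSE)
  if (n_tip_only)
    tree <- ape::keep.tip(tree, shared)
  if (n_grid_only) {
    presence <- grid$presence[shared, , drop = FALSE]
    keep_cells <- Matrix::colSums(presence) > 0
    grid <- occurrence_grid(presence[, keep_cells, drop = FALSE],
                            grid$cells[keep_cells, , drop = FALSE])
  }
  list(tree = tree, grid = grid)
}

#' Read and write long-format occurrence CSV
#'
#' The CSV has columns `species,cell_id`; cells not listed in `cells` raise an
#' error.
#'
#' @param path CSV file path.
#' @param cells data.frame of grid cells (`id`, `x`, `y`).
#' @return [occurrence_grid()].
#' @export
read_occurrences <- function(path, cells) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_grid(rec, cells)
}

#' @rdname read_occurrences
#' @param grid an [occurrence_grid()] to write.
#' @export
write_occurrences <- function(grid, path) {
  stopifnot(inherits(grid, "occurrence_grid"))
  trip <- methods::as(grid$presence, "TsparseMatrix")
  rec <- data.frame(species = rownames(grid$presence)[trip@i + 1L],
                    cell_id = colnames(grid$presence)[trip@j + 1L])
  rec <- rec[order(rec$species, rec$cell_id), ]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lay out a rectangular lattice of grid cells
#'
#' Helper for synthetic scenarios and examples: `nx * ny` unit-spaced square
#' cells with ids `c<row>_<col>`.
#'
#' @param nx,ny lattice dimensions.
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
lattice_cells <- function(nx, ny) {
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  data.frame(id = sprintf("c%d_%d", g$row, g$col),
             x = as.numeric(g$col), y = as.numeric(g$row))
}
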