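#' Construct a protection scheme from a binary mask
#'
#' A protection scheme is a per-cell binary protected flag. "Protected" means
#' any overlap at cell resolution (a cell counts as protected if any protected
#' area touches it); provenance filters applied upstream of the mask (e.g.
#' IUCN categories, designation status) can be recorded in `metadata`.
#'
#' @param protected named logical (or 0/1) vector keyed by cell id.
#' @param name scheme name (e.g. "existing_PA", "top30", "custom").
#' @param metadata optional list of provenance fields.
#' @return object of class `protection_scheme`.
#' @export
protection_scheme <- function(protected, name = "custom", metadata = list()) {
  if (is.null(names(protected))) stopf("`protected` must be named by cell id")
  flags <- as.logical(protected)
  if (anyNA(flags)) stopf("protected flags must be binary")
  structure(list(name = name,
                 protected = stats::setNames(flags, names(protected)),
                 metadata = metadata),
            class = "protection_scheme")
}

#' @export
print.protection_scheme <- function(x, ...) {
  cat(sprintf("<protection_scheme> '%s': %d of %d cells protected (%.1f%%)\n",
              x$name, sum(x$protected), length(x$protected),
              100 * mean(x$protected)))
  invisible(x)
}

#' Top-fraction priority mask
#'
#' Flags the best-ranked `ceiling(fraction * n)` cells of a priority ranking
#' as protected, the construction behind the top 17% / 30% / 50% conservation
#' targets. Rank 1 is the highest priority; ties across the cut boundary are
#' resolved by stable cell order (a message notes when this happens). Masks
#' from the same ranking are nested: top17 within top30 within top50.
#'
#' @param priority_rank named numeric layer; smaller values = higher priority.
#' @param fraction fraction of cells to protect, in (0, 1].
#' @param name optional scheme name; defaults to `top<percent>`.
#' @return a [protection_scheme()].
#' @export
priority_mask <- function(priority_rank, fraction, name = NULL) {
  if (is.null(names(priority_rank))) stopf("`priority_rank` must be named by cell id")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stopf("`fraction` must be in (0, 1]")
  n <- length(priority_rank)
  n_protect <- as.integer(ceiling(fraction * n))
  ord <- order(priority_rank, seq_len(n))  # stable on ties
  if (n_protect < n) {
    cut_val <- priority_rank[ord[n_protect]]
    if (sum(priority_rank <= cut_val) > n_protect)
      message("priority ties across the cut boundary resolved by stable cell order")
  }
  flags <- stats::setNames(rep(FALSE, n), names(priority_rank))
  flags[ord[seq_len(n_protect)]] <- TRUE
  protection_scheme(flags,
                    name = name %||% sprintf("top%d", round(100 * fraction)),
                    metadata = list(fraction = fraction))
}

#' Hotspot-class protection coverage
#'
#' Partitions the shared analysed cells into four classes - hotspots of
#' classification A only, of B only, joint hotspots, and non-hotspots - and
#' reports the percentage of each class covered by the protection scheme.
#' Classes with zero cells are reported as `NA` (undefined) rather than 0.
#'
#' @param class_a,class_b [canape_classify()] results (e.g. two taxonomic
#'   groups); pass the same object twice for a single-group analysis, which
#'   collapses A-only and joint.
#' @param scheme a [protection_scheme()] covering the analysed cells.
#' @param labels length-2 character names for the two groups.
#' @return data.frame with one row per class: `class`, `n_cells`,
#'   `n_protected`, `percentage` (1-decimal, half away from zero),
#'   `fraction`; overall coverage is attached as attribute `"overall"`.
#' @export
coverage_by_class <- function(class_a, class_b, scheme, labels = c("A", "B")) {
  stopifnot(inherits(class_a, "canape_classification"),
            inherits(class_b, "canape_classification"),
            inherits(scheme, "protection_scheme"))
  universe <- intersect(class_a$cell[class_a$category != "excluded"],
                        class_b$cell[class_b$category != "excluded"])
  if (!all(universe %in% names(scheme$protected)))
    stopf("protection scheme does not cover all analysed cells")
  hot_a <- universe %in% class_a$cell[class_a$hotspot]
  hot_b <- universe %in% class_b$cell[class_b$hotspot]
  cls <- ifelse(hot_a & hot_b, "joint",
                ifelse(hot_a, paste0(labels[1], "_only"),
                       ifelse(hot_b, paste0(labels[2], "_only"),
                              "non_hotspot")))
  cls <- factor(cls, levels = c(paste0(labels[1], "_only"),
                                paste0(labels[2], "_only"),
                                "joint", "non_hotspot"))
  prot <- scheme$protected[universe]
  rows <- lapply(levels(cls), function(k) {
    sel <- cls == k
    n_k <- sum(sel)
    n_p <- sum(prot[sel])
    data.frame(class = k, n_cells = n_k, n_protected = n_p,
               percentage = if (n_k > 0) as.numeric(report_percentage(n_p, n_k)) else NA_real_,
               fraction = if (n_k > 0) n_p / n_k else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$scheme <- scheme$name
  attr(out, "overall") <- as.numeric(report_percentage(sum(prot), length(universe)))
  out
}

#' Write a protection scheme as CSV
#'
#' @param scheme a [protection_scheme()].
#' @param path output CSV path.
#' @export
write_protection <- function(scheme, path) {
  stopifnot(inherits(scheme, "protection_scheme"))
  utils::write.csv(data.frame(cell_id = names(scheme$protected),
                              protected = as.integer(scheme$protected)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
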