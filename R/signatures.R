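# Cell-type marker derivation and signature building from labelled
# single-cell data, plus the gene-wise [0,1] scaling shared by the
# proteomic and transcriptomic matrices before deconvolution.

# counts-per-million normalization
#' @noRd
cpm <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
}

#' Derive per-type marker gene sets from labelled single cells
#'
#' For every cell type, genes are ranked one-vs-rest by log2 fold change
#' of mean normalized expression (counts-per-million, pseudocount 1),
#' requiring detection in at least `min_detect` of the type's cells and a
#' strictly positive fold change. Ties are broken by higher detection
#' fraction, then gene ID. The top `n` genes per type are returned.
#'
#' @param cells a `cell_matrix` from [gen_single_cell_counts()] or a list
#'   with `counts` (genes x cells) and `labels` (cell to cell-type).
#' @param n markers per type (default 100).
#' @param min_detect minimum detection fraction within the type.
#' @return named list of class `marker_sets`: one ordered character vector
#'   of gene IDs per cell type (possibly shorter than `n`, possibly empty
#'   with a warning).
#' @export
derive_markers <- function(cells, n = 100, min_detect = 0.1) {
  counts <- cells$counts
  labels <- cells$labels
  types <- unique(labels)
  if (length(types) < 2) stop2("need at least 2 cell types")
  norm <- cpm(counts)
  out <- vector("list", length(types))
  names(out) <- types
  for (k in types) {
    in_k <- labels == k
    if (sum(in_k) < 1) stop2("cell type ", k, " has no cells")
    m_in <- rowMeans(norm[, in_k, drop = FALSE])
    m_out <- rowMeans(norm[, !in_k, drop = FALSE])
    lfc <- log2(m_in + 1) - log2(m_out + 1)
    detect <- rowMeans(counts[, in_k, drop = FALSE] > 0)
    qual <- detect >= min_detect & lfc > 0
    if (!any(qual)) {
      warning("no qualifying marker genes for cell type ", k)
      out[[k]] <- character(0)
      next
    }
    ord <- order(-lfc[qual], -detect[qual], rownames(counts)[qual])
    out[[k]] <- utils::head(rownames(counts)[qual][ord], n)
  }
  structure(out, class = c("marker_sets", "list"), n = n)
}

#' Build a cell-type signature matrix from labelled single cells
#'
#' Entry (g, k) is the log2 mean normalized expression (CPM + 1) of gene
#' g across cells of type k, restricted to the union of marker genes
#' (or all genes when `markers` is `NULL`). Column order follows the
#' marker-set order when markers are given, otherwise label order.
#'
#' @param cells a `cell_matrix` (see [derive_markers()]).
#' @param markers a `marker_sets` list, or `NULL` for all genes.
#' @return numeric matrix (genes x cell types), log2 scale.
#' @export
build_signature_matrix <- function(cells, markers = NULL) {
  counts <- cells$counts
  labels <- cells$labels
  types <- if (!is.null(markers)) names(markers) else unique(labels)
  genes <- if (!is.null(markers)) {
    g <- unique(unlist(markers, use.names = FALSE))
    missing <- setdiff(g, rownames(counts))
    if (length(missing)) stop2("marker gene(s) absent from counts: ",
                               paste(head(missing, 5), collapse = ", "))
    intersect(rownames(counts), g)   # keep count-matrix order
  } else rownames(counts)
  norm <- cpm(counts)[genes, , drop = FALSE]
  sig <- sapply(types, function(k) {
    in_k <- labels == k
    if (sum(in_k) == 1) {
      warning("cell type ", k, " has a single cell; signature equals that cell")
    }
    log2(rowMeans(norm[, in_k, drop = FALSE]) + 1)
  })
  sig <- matrix(sig, nrow = length(genes), dimnames = list(genes, types))
  sig
}

#' Gene-wise min-max scaling to the unit interval
#'
#' Per feature (row), maps x to (x - min) / (max - min), bounding every
#' row to [0, 1]. Degenerate rows (max equal to min) map to all zeros and
#' are flagged rather than dropped. The per-row min/max are retained so
#' the transform is documented and invertible.
#'
#' @param x numeric matrix, no missing values.
#' @return matrix of class `scaled_matrix` with attributes `x_min`,
#'   `x_max` (per row) and `degenerate` (logical per row).
#' @export
minmax_scale <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop2("minmax_scale requires a complete matrix")
  mn <- apply(x, 1, min)
  mx <- apply(x, 1, max)
  rng <- mx - mn
  deg <- rng <= 0
  rng[deg] <- 1
  out <- (x - mn) / rng
  out[deg, ] <- 0
  structure(out, x_min = mn, x_max = mx, degenerate = deg,
            class = c("scaled_matrix", class(out)))
}
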