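# Plain-text readers and writers for the pipeline's interchange formats:
# intensity TSV (features x samples, "NA" for missing), sample-group TSV,
# GMT gene sets, Ct/AmpScore CSV pairs, ligand-receptor TSV, MatrixMarket
# counts with a labels TSV, and a JSON sidecar for simulation ground truth.

# Fail fast on ragged delimited files, reporting the offending line.
#' @noRd
check_rectangular <- function(path, sep = "\t") {
  n <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(n)) > 1) {
    bad <- which(n != n[1])[1]
    stop2("malformed table in '", path, "': line ", bad, " has ", n[bad],
          " fields, expected ", n[1])
  }
  invisible(TRUE)
}

#' Write / read a log2 intensity matrix as TSV
#'
#' Rows are features; the first column (`feature`) holds feature IDs;
#' missing entries are written as `NA`.
#'
#' @param m an [ev_matrix()] (writer) .
#' @param path file path.
#' @param groups (reader) two-group sample assignment; when `NULL` the
#'   reader looks for `<path>.groups.tsv` written by the writer.
#' @return the path (writer, invisibly) or an [ev_matrix()] (reader).
#' @export
write_intensity_tsv <- function(m, path) {
  stopifnot(inherits(m, "ev_matrix"))
  df <- data.frame(feature = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_groups_tsv(m$groups, paste0(path, ".groups.tsv"))
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path, groups = NULL) {
  check_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (is.null(groups)) {
    gpath <- paste0(path, ".groups.tsv")
    if (!file.exists(gpath)) stop2("no groups given and '", gpath, "' not found")
    groups <- read_groups_tsv(gpath)
  }
  ev_matrix(vals, groups)
}

#' Write / read a sample-group assignment TSV
#'
#' Two columns: `sample`, `group`.
#'
#' @param groups named character vector (sample to group).
#' @param path file path.
#' @return the path (writer, invisibly) or a named character vector.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_groups_tsv
#' @export
read_groups_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions.
#' @return the path (writer, invisibly) or a named list (reader).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write / read a Ct matrix as a CSV pair
#'
#' `path` receives the Ct values, `<path>.amp.csv` the amplification
#' scores, `<path>.groups.tsv` the group assignment.
#'
#' @param m a [ct_matrix()].
#' @param path CSV path for the Ct values.
#' @return the path (writer, invisibly) or a [ct_matrix()] (reader).
#' @export
write_ct_csv <- function(m, path) {
  stopifnot(inherits(m, "ct_matrix"))
  utils::write.csv(data.frame(mirna = rownames(m$ct), m$ct, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(mirna = rownames(m$amp), m$amp, check.names = FALSE),
                   paste0(path, ".amp.csv"), row.names = FALSE, quote = FALSE)
  write_groups_tsv(m$groups, paste0(path, ".groups.tsv"))
  invisible(path)
}

#' @rdname write_ct_csv
#' @param ... thresholds forwarded to [ct_matrix()].
#' @export
read_ct_csv <- function(path, groups = NULL, ...) {
  check_rectangular(path, sep = ",")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ct <- as.matrix(df[, -1, drop = FALSE])
  rownames(ct) <- df[[1]]
  adf <- utils::read.csv(paste0(path, ".amp.csv"), check.names = FALSE,
                         stringsAsFactors = FALSE)
  amp <- as.matrix(adf[, -1, drop = FALSE])
  rownames(amp) <- adf[[1]]
  if (is.null(groups)) groups <- read_groups_tsv(paste0(path, ".groups.tsv"))
  ct_matrix(ct, amp, groups, ...)
}

#' Write / read single-cell counts as MatrixMarket plus labels TSV
#'
#' `path` receives the sparse counts (`.mtx`); `<path>.genes.tsv`,
#' `<path>.cells.tsv` hold the dimension names, the latter with the
#' cell-type label column.
#'
#' @param cells a `cell_matrix`.
#' @param path `.mtx` path.
#' @return the path (writer, invisibly) or a `cell_matrix` (reader).
#' @export
write_cells_mtx <- function(cells, path) {
  Matrix::writeMM(Matrix::Matrix(cells$counts, sparse = TRUE), path)
  writeLines(rownames(cells$counts), paste0(path, ".genes.tsv"))
  utils::write.table(data.frame(cell = colnames(cells$counts),
                                label = unname(cells$labels)),
                     paste0(path, ".cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_mtx
#' @export
read_cells_mtx <- function(path) {
  counts <- as.matrix(Matrix::readMM(path))
  genes <- readLines(paste0(path, ".genes.tsv"))
  cdf <- utils::read.delim(paste0(path, ".cells.tsv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cdf$cell)
  structure(list(counts = counts,
                 labels = stats::setNames(cdf$label, cdf$cell),
                 dispersion = NA_real_),
            class = "cell_matrix")
}

#' Write / read a ligand-receptor table as TSV
#'
#' @param lr data.frame with `ligand`, `receptor` (and optionally
#'   `complex`) columns.
#' @param path file path.
#' @return the path (writer, invisibly) or a data.frame (reader).
#' @export
write_lr_tsv <- function(lr, path) {
  utils::write.table(lr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lr_tsv
#' @export
read_lr_tsv <- function(path) {
  check_rectangular(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a simulation ground-truth sidecar as JSON
#'
#' @param truth a [sim_truth()] object.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_sim_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(proportions = as.data.frame(truth$proportions),
         samples = rownames(truth$proportions),
         groups = as.list(truth$groups),
         de_features = as.list(truth$de_features),
         dropout_rate = truth$dropout_rate, noise_sd = truth$noise_sd,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
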