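# Ligand-receptor analysis: join differentially expressed EV proteins to
# a curated interaction table, build receptor modules for up- and
# down-regulated ligands, and score module enrichment across cell types.

# Validate / normalize an interaction table; expand optional receptor
# complexes (a `complex` column with ';'-separated subunit genes) into
# one row per subunit gene.
#' @noRd
normalize_lr <- function(lr) {
  if (!all(c("ligand", "receptor") %in% names(lr))) {
    stop2("interaction table needs 'ligand' and 'receptor' columns")
  }
  lr$ligand <- toupper(lr$ligand)
  lr$receptor <- toupper(lr$receptor)
  if ("complex" %in% names(lr)) {
    has <- !is.na(lr$complex) & nzchar(lr$complex)
    if (any(has)) {
      extra <- do.call(rbind, lapply(which(has), function(i) {
        subunits <- toupper(strsplit(lr$complex[i], ";")[[1]])
        data.frame(ligand = lr$ligand[i], receptor = subunits,
                   stringsAsFactors = FALSE)
      }))
      lr <- rbind(lr[, c("ligand", "receptor")], extra)
    } else lr <- lr[, c("ligand", "receptor")]
  } else lr <- lr[, c("ligand", "receptor")]
  unique(lr)
}

#' Split differentially expressed features into up/down ligands
#'
#' Applies the DE thresholds (strict: `p < p_cut` and `|logFC| > lfc_cut`)
#' and keeps the features present as ligands in the interaction table,
#' split by fold-change sign.
#'
#' @param de an `ev_de` data.frame (see [ebayes_moderate()]).
#' @param lr interaction table with `ligand`/`receptor` columns.
#' @param p_cut,lfc_cut DE thresholds.
#' @return list with character vectors `up` and `down`.
#' @export
extract_de_ligands <- function(de, lr, p_cut = 0.05, lfc_cut = 0.5) {
  stopifnot(inherits(de, "ev_de"))
  lr <- normalize_lr(lr)
  sig <- de[de$p < p_cut & abs(de$logFC) > lfc_cut, , drop = FALSE]
  feat <- toupper(sig$feature)
  is_lig <- feat %in% lr$ligand
  list(up = sort(unique(feat[is_lig & sig$logFC > 0])),
       down = sort(unique(feat[is_lig & sig$logFC < 0])))
}

#' Map ligands to their receptors
#'
#' Returns every interaction row whose ligand is in the input, with a
#' topology summary (distinct ligands found, distinct receptors, number
#' of interactions).
#'
#' @param ligands character vector of ligand gene symbols.
#' @param lr interaction table.
#' @return list with `interactions` (data.frame) and `summary`
#'   (`n_ligands`, `n_receptors`, `n_interactions`).
#' @export
map_receptors <- function(ligands, lr) {
  lr <- normalize_lr(lr)
  rows <- lr[lr$ligand %in% toupper(ligands), , drop = FALSE]
  rownames(rows) <- NULL
  list(interactions = rows,
       summary = list(n_ligands = length(unique(rows$ligand)),
                      n_receptors = length(unique(rows$receptor)),
                      n_interactions = nrow(rows)))
}

#' Build receptor modules for up- and down-regulated ligands
#'
#' One module per fold-change direction: the union of receptors of that
#' direction's ligands.
#'
#' @param de_ligands output of [extract_de_ligands()].
#' @param lr interaction table.
#' @return list of class `receptor_modules` with elements `up` and `down`,
#'   each a list of `receptors` and `source_ligands`.
#' @export
receptor_modules <- function(de_ligands, lr) {
  lr <- normalize_lr(lr)
  mk <- function(ligs) {
    rows <- lr[lr$ligand %in% ligs, , drop = FALSE]
    list(receptors = sort(unique(rows$receptor)), source_ligands = ligs)
  }
  structure(list(up = mk(de_ligands$up), down = mk(de_ligands$down)),
            class = "receptor_modules")
}

#' Score receptor-module enrichment across cell types
#'
#' Scores each direction's receptor module against cell-type expression
#' profiles. Default method is preranked GSEA on per-type specificity
#' z-scores (delegating to [celltype_target_enrichment()]); the `zscore`
#' alternative uses the mean specificity z of the module genes with a
#' gene-label permutation p-value.
#'
#' @param modules a `receptor_modules` object (or any named list of gene
#'   sets).
#' @param profiles log2-scale signature matrix (genes x cell types).
#' @param n_perm,seed permutation settings.
#' @param method `"gsea"` or `"zscore"`.
#' @return an `ev_enrich_grid` data.frame (see
#'   [celltype_target_enrichment()]); for `method = "zscore"` the `es`
#'   column holds the mean module z-score and `nes`/`leading_edge` are
#'   empty.
#' @export
score_modules <- function(modules, profiles, n_perm = 1000, seed = 1L,
                          method = c("gsea", "zscore")) {
  method <- match.arg(method)
  sets <- if (inherits(modules, "receptor_modules")) {
    list(up = modules$up$receptors, down = modules$down$receptors)
  } else modules
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  profiles <- as.matrix(profiles)
  ok <- vapply(sets, function(s) length(intersect(s, rownames(profiles))) > 0,
               logical(1))
  if (any(!ok)) {
    warning("module(s) with no genes in the profiles skipped: ",
            paste(names(sets)[!ok], collapse = ", "))
    sets <- sets[ok]
  }
  if (!length(sets)) stop2("no module intersects the profile genes")
  if (method == "gsea") {
    return(celltype_target_enrichment(sets, profiles, n_perm = n_perm,
                                      seed = seed))
  }
  mu <- rowMeans(profiles)
  sdv <- apply(profiles, 1, stats::sd)
  sdv[sdv <= 0] <- 1
  z <- (profiles - mu) / sdv
  cell <- 0L
  rows <- list()
  for (k in colnames(profiles)) {
    for (s in names(sets)) {
      cell <- cell + 1L
      idx <- rownames(profiles) %in% sets[[s]]
      stat <- mean(z[idx, k])
      perm <- with_seed(seed + cell, {
        vapply(seq_len(n_perm), function(i) {
          mean(z[sample.int(nrow(z), sum(idx)), k])
        }, numeric(1))
      })
      p <- (1 + sum(abs(perm) >= abs(stat) - 1e-12)) / (n_perm + 1)
      rows[[cell]] <- data.frame(set = s, cell_type = k, es = stat,
                                 nes = NA_real_, p = p, size = sum(idx),
                                 leading_edge = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "cell_type", "es", "nes", "p", "p_adj", "size",
                 "leading_edge")]
  class(out) <- c("ev_enrich_grid", "data.frame")
  out
}
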