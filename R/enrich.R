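# Preranked gene-set enrichment with permutation p-values and
# leading-edge extraction, hypergeometric over-representation, and the
# per-cell-type target-set enrichment grid.
#
# Running-sum convention: walking down the ranked list, each gene-set hit
# adds its normalized weight |metric|^weight / sum(|metric|^weight over
# the set), and every position (hit or miss) subtracts the uniform 1/N.
# The enrichment score is the running sum at its maximum absolute
# deviation from zero, so a set occupying the top |S| ranks at weight 0
# scores 1 - |S|/N.

# Sort a named metric vector descending with a stable gene-ID tie-break.
#' @noRd
rank_metric <- function(metric) {
  if (is.null(names(metric))) stop2("ranking metric must be named by gene")
  if (anyDuplicated(names(metric))) stop2("duplicate genes in ranked list")
  metric[order(-metric, names(metric))]
}

# ES and extremum position for hit indicator vector `hit` (logical, in
# rank order) with weights `w` (|metric|^weight, in rank order).
#' @noRd
running_es <- function(hit, w) {
  n <- length(hit)
  hw <- w * hit
  tot <- sum(hw)
  if (tot <= 0) hw[hit] <- 1 / sum(hit) else hw <- hw / tot
  run <- cumsum(unname(hw)) - seq_len(n) / n
  i <- which.max(abs(run))
  list(es = run[i], pos = i)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the running-sum enrichment score of `gene_set` along the
#' ranked list, a gene-label permutation p-value (fraction of random
#' placements of the set with `|ES|` at least as large, with add-one
#' correction), the normalized enrichment score (ES divided by the mean
#' `|ES|` of same-signed permutations) and the leading edge: set members
#' at or before the running-sum extremum for positive ES, at or after it
#' for negative ES.
#'
#' With `exact = TRUE` the p-value is computed by exhaustive enumeration
#' of all `choose(N, |S|)` placements instead of random sampling (the
#' observed placement is one of them, so p >= 1/choose(N, |S|)).
#'
#' @param ranked named numeric vector (gene -> metric); sorted internally
#'   in descending order, ties broken by gene ID.
#' @param gene_set character vector of genes; must intersect the list.
#' @param n_perm number of gene-label permutations.
#' @param weight exponent on |metric| for hit increments (0 = unweighted).
#' @param seed integer seed for the permutations.
#' @param exact exhaustively enumerate placements (feasible only for
#'   small lists; enforced limit `choose(N, |S|) <= 2e5`).
#' @return list of class `enrichment_result`: `es`, `nes`, `p`,
#'   `leading_edge`, `size` (set members in the list), `n_perm`,
#'   `degenerate` (TRUE when the set covers the whole list).
#' @export
gsea_preranked <- function(ranked, gene_set, n_perm = 1000, weight = 1,
                           seed = 1L, exact = FALSE) {
  stopifnot(n_perm >= 1)
  metric <- rank_metric(ranked)
  genes <- names(metric)
  n <- length(genes)
  hit <- genes %in% gene_set
  k <- sum(hit)
  if (k == 0) stop2("gene set does not intersect the ranked list")
  degenerate <- k == n
  if (degenerate) warning("gene set covers the entire ranked list")
  w <- abs(metric)^weight
  obs <- running_es(hit, w)
  es <- obs$es
  le <- if (es >= 0) genes[seq_len(obs$pos)][hit[seq_len(obs$pos)]] else
    genes[obs$pos:n][hit[obs$pos:n]]

  eps <- 1e-12
  if (exact) {
    if (choose(n, k) > 2e5) stop2("exact enumeration infeasible: choose(N, |S|) > 2e5")
    combs <- utils::combn(n, k)
    es_perm <- apply(combs, 2, function(idx) {
      h <- logical(n)
      h[idx] <- TRUE
      running_es(h, w)$es
    })
    p <- mean(abs(es_perm) >= abs(es) - eps)
    n_used <- ncol(combs)
  } else {
    es_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        h <- logical(n)
        h[sample.int(n, k)] <- TRUE
        running_es(h, w)$es
      }, numeric(1))
    })
    p <- (1 + sum(abs(es_perm) >= abs(es) - eps)) / (n_perm + 1)
    n_used <- n_perm
  }
  same_sign <- es_perm[sign(es_perm) == sign(es) & es_perm != 0]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NaN
  structure(list(es = es, nes = nes, p = p, leading_edge = le,
                 size = k, n_perm = n_used, degenerate = degenerate),
            class = "enrichment_result")
}

#' Hypergeometric over-representation test
#'
#' Exact upper-tail probability of observing at least the seen overlap
#' between a hit list and a gene set drawn from a finite universe:
#' `P(X >= k)` for X hypergeometric with `|gene_set|` successes among
#' `|universe|` and `|hits|` draws.
#'
#' @param hits,gene_set,universe character vectors; `hits` and `gene_set`
#'   must be subsets of `universe`.
#' @return list with `p`, `overlap`, `expected` (expected overlap under
#'   the null) and the three set sizes.
#' @export
ora_hypergeom <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  hits <- unique(hits)
  gene_set <- unique(gene_set)
  if (!all(hits %in% universe)) stop2("hits must be a subset of the universe")
  if (!all(gene_set %in% universe)) stop2("gene_set must be a subset of the universe")
  N <- length(universe)
  K <- length(gene_set)
  n <- length(hits)
  k <- length(intersect(hits, gene_set))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = k, expected = n * K / N, n_universe = N,
       n_set = K, n_hits = n)
}

#' Per-cell-type enrichment of target gene sets
#'
#' For every cell type, genes are ranked by specificity -- the z-score of
#' that type's expression across cell types (per gene) -- and each target
#' set is scored with [gsea_preranked()]. Benjamini-Hochberg adjustment
#' is applied across the whole set x type grid.
#'
#' @param target_sets named list of gene sets (e.g. per miRNA targetome,
#'   or receptor modules).
#' @param profiles log2-scale signature matrix (genes x cell types).
#' @param n_perm,weight,seed passed to [gsea_preranked()]; each grid cell
#'   uses a seed derived deterministically from `seed`.
#' @return data.frame of class `ev_enrich_grid`: `set`, `cell_type`, `es`,
#'   `nes`, `p`, `p_adj`, `size`, `leading_edge` (comma-separated).
#' @export
celltype_target_enrichment <- function(target_sets, profiles, n_perm = 1000,
                                       weight = 1, seed = 1L) {
  profiles <- as.matrix(profiles)
  if (is.null(names(target_sets))) stop2("target_sets must be named")
  keep <- vapply(target_sets, function(s) length(intersect(s, rownames(profiles))) > 0,
                 logical(1))
  if (!all(keep)) {
    warning("dropping target set(s) with no genes in the profiles: ",
            paste(names(target_sets)[!keep], collapse = ", "))
    target_sets <- target_sets[keep]
  }
  if (!length(target_sets)) stop2("no target set intersects the profile genes")
  mu <- rowMeans(profiles)
  sdv <- apply(profiles, 1, stats::sd)
  sdv[sdv <= 0] <- 1
  z <- (profiles - mu) / sdv
  cell <- 0L
  rows <- list()
  for (ki in seq_along(colnames(profiles))) {
    k <- colnames(profiles)[ki]
    ranked <- stats::setNames(z[, k], rownames(profiles))
    for (s in names(target_sets)) {
      cell <- cell + 1L
      # the permutation seed depends only on the cell type and set size,
      # so identical gene sets receive identical scores
      r <- gsea_preranked(ranked, target_sets[[s]], n_perm = n_perm,
                          weight = weight,
                          seed = seed + 7919L * ki + length(target_sets[[s]]))
      rows[[cell]] <- data.frame(set = s, cell_type = k, es = r$es,
                                 nes = r$nes, p = r$p, size = r$size,
                                 leading_edge = paste(r$leading_edge, collapse = ","),
                                 stringsAsFactors = FALSE)
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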