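# Synthetic-data generators with known ground truth.
#
# Every generator here is a pure function of its parameters and seed:
# calling it twice with the same arguments returns bit-identical output,
# and the caller's RNG state is never touched.

#' Ground truth for a simulated EV proteome cohort
#'
#' Bundles the quantities that the downstream pipeline is supposed to
#' recover: per-sample cell-type fractions, the spiked group effects, and
#' the noise/dropout settings used by [gen_ev_proteome()].
#'
#' @param proportions numeric matrix, samples x cell types; each row must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param groups character vector mapping each sample (rows of
#'   `proportions`) to one of two group labels; defaults to the first half
#'   `"control"`, second half `"case"`.
#' @param de_features named numeric vector of true group log2 fold changes
#'   (case minus control) for spiked features; may be empty.
#' @param dropout_rate target fraction of entries set missing, in `[0, 1)`.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   log2-intensity scale.
#' @param seed integer seed consumed by [gen_ev_proteome()].
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(proportions, groups = NULL, de_features = numeric(0),
                      dropout_rate = 0, noise_sd = 0, seed = 1L) {
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions))) {
    rownames(proportions) <- sprintf("S%02d", seq_len(nrow(proportions)))
  }
  if (any(proportions < -1e-12)) stop2("proportions must be non-negative")
  sums <- rowSums(proportions)
  if (any(abs(sums - 1) > 1e-9)) {
    stop2("each sample's cell-type fractions must sum to 1 (max deviation ",
          format(max(abs(sums - 1))), ")")
  }
  n <- nrow(proportions)
  if (is.null(groups)) {
    groups <- rep(c("control", "case"), c(ceiling(n / 2), floor(n / 2)))
  }
  names(groups) <- rownames(proportions)
  if (!(dropout_rate >= 0 && dropout_rate < 1)) stop2("dropout_rate must be in [0, 1)")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (length(de_features) && is.null(names(de_features))) {
    stop2("de_features must be a named vector of log2 fold changes")
  }
  structure(
    list(proportions = proportions, groups = groups,
         de_features = de_features, dropout_rate = dropout_rate,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_truth")
}

#' Random per-sample cell-type fractions
#'
#' Draws each sample's fraction vector from a Dirichlet distribution
#' centred on `means` with concentration `concentration` (larger =
#' tighter around the mean). Used to give cohorts realistic
#' sample-to-sample compositional variation.
#'
#' @param n_samples number of samples.
#' @param means named numeric vector of mean fractions (normalized internally).
#' @param concentration Dirichlet concentration (sum of alpha); default 200.
#' @param seed integer seed.
#' @return samples x cell-type matrix of fractions, rows summing to 1.
#' @export
random_proportions <- function(n_samples, means, concentration = 200, seed = 1L) {
  means <- means / sum(means)
  with_seed(seed, {
    a <- means * concentration
    g <- matrix(stats::rgamma(n_samples * length(a), shape = rep(a, each = n_samples)),
                nrow = n_samples)
    p <- g / rowSums(g)
    dimnames(p) <- list(sprintf("S%02d", seq_len(n_samples)), names(means))
    p
  })
}

#' Simulate cell-type expression signatures with planted markers
#'
#' Builds a log2-scale signature matrix in which every cell type has
#' `n_markers_per_type` dedicated marker genes elevated by
#' `marker_log2fc` over a shared log-normal baseline (mean
#' `baseline_mean`, sd `baseline_sd` on the log2 scale). Marker sets are
#' pairwise disjoint by construction.
#'
#' @param n_genes number of genes.
#' @param n_celltypes number of cell types.
#' @param n_markers_per_type markers planted per type; the total must not
#'   exceed `n_genes`.
#' @param marker_log2fc elevation of markers over baseline (log2 units, > 0
#'   for informative signatures; 0 yields identical columns).
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd log2-scale baseline distribution.
#' @param celltype_names optional character vector of type names
#'   (default `CT1..CTk`).
#' @return list with `signature` (genes x types, log2 scale), `markers`
#'   (named list of marker gene IDs per type) and `baseline`.
#' @export
gen_cell_signatures <- function(n_genes = 1000, n_celltypes = 5,
                                n_markers_per_type = 100, marker_log2fc = 3,
                                seed = 1L, baseline_mean = 5, baseline_sd = 1.5,
                                celltype_names = NULL) {
  if (n_markers_per_type * n_celltypes > n_genes) {
    stop2("infeasible marker allocation: ", n_markers_per_type, " markers x ",
          n_celltypes, " types > ", n_genes, " genes")
  }
  if (marker_log2fc < 0) stop2("marker_log2fc must be >= 0")
  types <- celltype_names %||% sprintf("CT%d", seq_len(n_celltypes))
  stopifnot(length(types) == n_celltypes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    names(baseline) <- genes
    marker_idx <- matrix(sample.int(n_genes, n_markers_per_type * n_celltypes),
                         ncol = n_celltypes)
    sig <- matrix(baseline, n_genes, n_celltypes,
                  dimnames = list(genes, types))
    markers <- vector("list", n_celltypes)
    names(markers) <- types
    for (k in seq_len(n_celltypes)) {
      sig[marker_idx[, k], k] <- sig[marker_idx[, k], k] + marker_log2fc
      markers[[k]] <- genes[sort(marker_idx[, k])]
    }
    list(signature = sig, markers = markers, baseline = baseline)
  })
}

#' Simulate an EV proteome as noisy convex mixtures of signatures
#'
#' Each sample's log2 intensity is `log2(sum_k p_k * 2^signature_k)` for
#' that sample's true fractions `p`, plus the spiked group effect for
#' `truth$de_features` in case samples, plus Gaussian noise. Entries are
#' then set missing with probability *decreasing* in the noiseless
#' intensity (left-censored, missing-not-at-random): a logistic curve
#' with midpoint at the noiseless matrix's lower quartile and width 1
#' log2 unit, whose amplitude is tuned so the expected global missing
#' rate equals `truth$dropout_rate`.
#'
#' @param signatures output of [gen_cell_signatures()] or a log2-scale
#'   genes x types matrix.
#' @param truth a [sim_truth()] object; its `proportions` columns must match
#'   the signature's cell types.
#' @param mnar_width logistic width of the dropout curve (log2 units).
#' @return an [ev_matrix()] with `NA` at dropped entries; the truth object
#'   is attached as attribute `"truth"`.
#' @export
gen_ev_proteome <- function(signatures, truth, mnar_width = 1) {
  sig <- if (is.list(signatures)) signatures$signature else signatures
  if (!inherits(truth, "sim_truth")) stop2("truth must be a sim_truth object")
  P <- truth$proportions
  if (!setequal(colnames(P), colnames(sig))) {
    stop2("truth proportions and signature matrix disagree on cell types")
  }
  P <- P[, colnames(sig), drop = FALSE]
  de <- truth$de_features
  if (length(de) && !all(names(de) %in% rownames(sig))) {
    stop2("de_features must be a subset of the signature's genes")
  }
  lv <- group_levels(truth$groups)
  case <- names(truth$groups)[truth$groups == lv[2]]
  with_seed(truth$seed, {
    lin <- 2^sig
    m0 <- log2(lin %*% t(P))            # genes x samples, noiseless mixture
    if (length(de)) m0[names(de), case] <- m0[names(de), case] + de
    vals <- m0 + stats::rnorm(length(m0), 0, truth$noise_sd)
    mask <- matrix(FALSE, nrow(m0), ncol(m0))
    if (truth$dropout_rate > 0) {
      mid <- stats::quantile(m0, 0.25)
      base <- stats::plogis((mid - m0) / mnar_width)
      amp <- truth$dropout_rate / mean(base)
      if (amp * max(base) > 1) {
        warning("dropout_rate not exactly attainable with this MNAR curve; ",
                "probabilities capped at 1")
      }
      pmiss <- pmin(amp * base, 1)
      mask <- matrix(stats::runif(length(m0)) < pmiss, nrow(m0), ncol(m0))
      vals[mask] <- NA_real_
    }
    dimnames(vals) <- dimnames(m0)
    out <- ev_matrix(vals, groups = truth$groups)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate labelled single-cell counts from signatures
#'
#' Draws negative-binomial counts per cell with per-gene mean proportional
#' to the (linear-scale) signature column of the cell's type, scaled to
#' `library_size`. `dispersion = 0` uses Poisson sampling.
#'
#' @param signatures output of [gen_cell_signatures()] or a log2-scale matrix.
#' @param cells_per_type cells per type (scalar or per-type vector, >= 2).
#' @param library_size expected total counts per cell.
#' @param dispersion negative-binomial dispersion (1/size); 0 = Poisson.
#' @param seed integer seed.
#' @return object of class `cell_matrix`: list with `counts` (genes x cells),
#'   `labels` (named character) and `dispersion`.
#' @export
gen_single_cell_counts <- function(signatures, cells_per_type = 50,
                                   library_size = 10000, dispersion = 0.3,
                                   seed = 1L) {
  sig <- if (is.list(signatures)) signatures$signature else signatures
  types <- colnames(sig)
  if (length(cells_per_type) == 1L) {
    cells_per_type <- rep(cells_per_type, length(types))
  }
  if (any(cells_per_type < 2)) stop2("cells_per_type must be >= 2")
  if (dispersion < 0) stop2("dispersion must be >= 0")
  with_seed(seed, {
    counts_by_type <- lapply(seq_along(types), function(k) {
      q <- 2^sig[, k]
      mu <- library_size * q / sum(q)
      n <- cells_per_type[k]
      m <- if (dispersion == 0) {
        matrix(stats::rpois(nrow(sig) * n, rep(mu, n)), nrow = nrow(sig))
      } else {
        matrix(stats::rnbinom(nrow(sig) * n, mu = rep(mu, n),
                              size = 1 / dispersion), nrow = nrow(sig))
      }
      m
    })
    counts <- do.call(cbind, counts_by_type)
    labels <- rep(types, cells_per_type)
    colnames(counts) <- sprintf("%s_c%03d", labels,
                                unlist(lapply(cells_per_type, seq_len)))
    rownames(counts) <- rownames(sig)
    names(labels) <- colnames(counts)
    structure(list(counts = counts, labels = labels, dispersion = dispersion),
              class = "cell_matrix")
  })
}

#' Simulate an OpenArray-style Ct matrix with amplification scores
#'
#' Ct values are Gaussian around a per-miRNA baseline (uniform on
#' `ct_baseline`); `n_de` randomly chosen miRNAs are shifted by
#' `de_delta_ct` in the case group (negative delta = upregulation, since
#' lower Ct means higher expression). A fraction of entries is made
#' unreliable by either dropping the amplification score below `amp_min`
#' or pushing Ct above `ct_max`.
#'
#' @param n_mirna,n_samples_per_group panel size and group size.
#' @param n_de number of differentially expressed miRNAs (`<= n_mirna`).
#' @param de_delta_ct Ct shift in the case group.
#' @param unreliable_fraction expected fraction of unreliable entries.
#' @param seed integer seed.
#' @param ct_baseline range of per-miRNA baseline Ct values.
#' @param noise_sd replicate noise on Ct.
#' @param ct_max,amp_min reliability thresholds stored on the result.
#' @return a [ct_matrix()]; true DE miRNA names and delta are attached as
#'   attribute `"truth"`.
#' @export
gen_ct_array <- function(n_mirna = 139, n_samples_per_group = 6, n_de = 35,
                         de_delta_ct = -1, unreliable_fraction = 0.05,
                         seed = 1L, ct_baseline = c(22, 32), noise_sd = 0.25,
                         ct_max = 35, amp_min = 1.24) {
  if (n_de > n_mirna) stop2("n_de must be <= n_mirna")
  if (unreliable_fraction < 0 || unreliable_fraction >= 1) {
    stop2("unreliable_fraction must be in [0, 1)")
  }
  n_samples <- 2L * n_samples_per_group
  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  samples <- sprintf("S%02d", seq_len(n_samples))
  groups <- stats::setNames(rep(c("control", "case"), each = n_samples_per_group),
                            samples)
  with_seed(seed, {
    baseline <- stats::runif(n_mirna, ct_baseline[1], ct_baseline[2])
    ct <- matrix(baseline, n_mirna, n_samples,
                 dimnames = list(mirnas, samples))
    ct <- ct + stats::rnorm(length(ct), 0, noise_sd)
    de_idx <- sort(sample.int(n_mirna, n_de))
    ct[de_idx, groups == "case"] <- ct[de_idx, groups == "case"] + de_delta_ct
    amp <- matrix(stats::runif(length(ct), amp_min + 0.06, 1.9),
                  n_mirna, n_samples, dimnames = dimnames(ct))
    if (unreliable_fraction > 0) {
      bad <- which(stats::runif(length(ct)) < unreliable_fraction)
      if (length(bad)) {
        # half fail on amplification quality, half on the Ct ceiling
        low_amp <- bad[stats::runif(length(bad)) < 0.5]
        high_ct <- setdiff(bad, low_amp)
        amp[low_amp] <- stats::runif(length(low_amp), 0.3, amp_min - 0.01)
        ct[high_ct] <- stats::runif(length(high_ct), ct_max + 0.5, 40)
      }
    }
    out <- ct_matrix(ct, amp, groups, ct_max = ct_max, amp_min = amp_min)
    attr(out, "truth") <- list(de_mirnas = mirnas[de_idx],
                               de_delta_ct = de_delta_ct)
    out
  })
}

#' Simulate a toy ligand-receptor interaction table
#'
#' Builds a bipartite (ligand, receptor) table. Each ligand receives
#' `receptors_per_ligand` partners; a fraction `shared_receptor_fraction`
#' of all pair slots reuses a receptor already assigned to an earlier
#' ligand, so the number of distinct receptors is deterministically
#' `sum(receptors_per_ligand) - round(shared_receptor_fraction * sum(...))`.
#'
#' @param n_ligands number of ligands.
#' @param receptors_per_ligand scalar or per-ligand integer vector.
#' @param shared_receptor_fraction fraction of interactions that reuse a
#'   receptor of another ligand, in `[0, 1)`.
#' @param seed integer seed.
#' @param ligand_names,receptor_names optional name pools.
#' @return data.frame with columns `ligand`, `receptor` (no duplicate pairs).
#' @export
gen_lr_database <- function(n_ligands = 6, receptors_per_ligand = 5,
                            shared_receptor_fraction = 0.2, seed = 1L,
                            ligand_names = NULL, receptor_names = NULL) {
  if (n_ligands < 1) stop2("n_ligands must be positive")
  if (length(receptors_per_ligand) == 1L) {
    receptors_per_ligand <- rep(receptors_per_ligand, n_ligands)
  }
  stopifnot(length(receptors_per_ligand) == n_ligands,
            all(receptors_per_ligand >= 1))
  if (shared_receptor_fraction < 0 || shared_receptor_fraction >= 1) {
    stop2("shared_receptor_fraction must be in [0, 1)")
  }
  total <- sum(receptors_per_ligand)
  n_shared <- round(shared_receptor_fraction * total)
  # shared slots can only reuse receptors introduced by earlier ligands,
  # so none may land on the first ligand
  ligs <- ligand_names %||% sprintf("LIG%02d", seq_len(n_ligands))
  recs <- receptor_names %||% sprintf("REC%03d", seq_len(total))
  if (length(recs) < total - n_shared) stop2("receptor name pool too small")
  with_seed(seed, {
    # choose which pair slots (beyond the first ligand's) are shared
    slot_lig <- rep(seq_len(n_ligands), receptors_per_ligand)
    eligible <- which(slot_lig > 1L)
    if (n_shared > length(eligible)) {
      stop2("shared_receptor_fraction too high for this ligand layout")
    }
    shared_slots <- if (n_shared > 0) sort(sample(eligible, n_shared)) else integer(0)
    receptor <- character(total)
    fresh <- 0L
    for (i in seq_len(total)) {
      if (i %in% shared_slots) {
        lig_i <- slot_lig[i]
        pool <- setdiff(unique(receptor[seq_len(i - 1)][slot_lig[seq_len(i - 1)] != lig_i]),
                        receptor[seq_len(i - 1)][slot_lig[seq_len(i - 1)] == lig_i])
        if (length(pool) == 0L) {          # cannot share without duplicating
          fresh <- fresh + 1L
          receptor[i] <- recs[fresh]
        } else {
          receptor[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
        }
      } else {
        fresh <- fresh + 1L
        receptor[i] <- recs[fresh]
      }
    }
    out <- data.frame(ligand = ligs[slot_lig], receptor = receptor,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out)) stop2("internal error: duplicate ligand-receptor pair")
    out
  })
}
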