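# Synthetic-data generators: determinism, planted structure, MNAR
# missingness, and the documented degenerate cases.

test_that("signature generator plants disjoint marker sets of the requested size", {
  gs <- gen_cell_signatures(1000, 5, 100, marker_log2fc = 3, seed = 1)
  expect_equal(dim(gs$signature), c(1000, 5))
  expect_true(all(lengths(gs$markers) == 100))
  all_markers <- unlist(gs$markers)
  expect_equal(anyDuplicated(all_markers), 0L)
  # markers are elevated by exactly the requested effect over baseline
  for (k in names(gs$markers)) {
    expect_equal(gs$signature[gs$markers[[k]], k] - gs$baseline[gs$markers[[k]]],
                 rep(3, 100), ignore_attr = TRUE)
  }
  expect_error(gen_cell_signatures(100, 5, 50), "infeasible")
})

test_that("zero marker effect gives identical signature columns", {
  gs <- gen_cell_signatures(300, 4, 40, marker_log2fc = 0, seed = 2)
  for (k in 2:4) expect_equal(gs$signature[, k], gs$signature[, 1])
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(gen_cell_signatures(200, 3, 20, seed = 9),
                   gen_cell_signatures(200, 3, 20, seed = 9))
  gs <- gen_cell_signatures(200, 3, 20, seed = 9)
  tr <- sim_truth(random_proportions(6, c(a = 1, b = 1, c = 1), seed = 3),
                  dropout_rate = 0.1, noise_sd = 0.2, seed = 4)
  colnames(tr$proportions) <- colnames(gs$signature)
  expect_identical(gen_ev_proteome(gs, tr)$values, gen_ev_proteome(gs, tr)$values)
  expect_identical(gen_single_cell_counts(gs, 5, seed = 5)$counts,
                   gen_single_cell_counts(gs, 5, seed = 5)$counts)
  expect_identical(gen_ct_array(seed = 6), gen_ct_array(seed = 6))
  expect_identical(gen_lr_database(seed = 7), gen_lr_database(seed = 7))
  # the caller's RNG stream is not consumed
  set.seed(11); before <- runif(1)
  set.seed(11); invisible(gen_cell_signatures(100, 2, 10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("pure single-type mixture reproduces the signature column exactly", {
  gs <- gen_cell_signatures(400, 4, 40, seed = 1)
  P <- rbind(S01 = c(1, 0, 0, 0), S02 = c(0, 1, 0, 0),
             S03 = c(1, 0, 0, 0), S04 = c(0, 1, 0, 0))
  colnames(P) <- colnames(gs$signature)
  m <- gen_ev_proteome(gs, sim_truth(P, seed = 2))
  expect_equal(unname(m$values[, "S01"]), unname(gs$signature[, 1]))
  expect_equal(unname(m$values[, "S02"]), unname(gs$signature[, 2]))
})

test_that("MNAR dropout hits the target rate and censors low intensities", {
  gs <- gen_cell_signatures(1000, 5, 100, seed = 1)
  P <- random_proportions(10, setNames(rep(1, 5), colnames(gs$signature)),
                          seed = 2)
  tr_drop <- sim_truth(P, dropout_rate = 0.2, noise_sd = 0.1, seed = 3)
  tr_full <- sim_truth(P, dropout_rate = 0, noise_sd = 0.1, seed = 3)
  m_drop <- gen_ev_proteome(gs, tr_drop)
  m_full <- gen_ev_proteome(gs, tr_full)
  # 10,000 entries: empirical missing fraction within +/- 0.02 of target
  expect_lt(abs(mean(m_drop$mask) - 0.2), 0.02)
  # left-censoring: true values behind missing entries are lower on average
  expect_gt(mean(m_full$values[!m_drop$mask]), mean(m_full$values[m_drop$mask]))
})

test_that("invalid proportions are rejected", {
  expect_error(sim_truth(matrix(c(0.5, 0.4, 0.6, 0.6), 2)), "sum to 1")
  expect_error(sim_truth(matrix(c(-0.1, 0.4, 1.1, 0.6), 2)), "non-negative")
})

test_that("single-cell counts follow the scaled signature means", {
  gs <- gen_cell_signatures(400, 3, 40, seed = 1)
  cm <- gen_single_cell_counts(gs, cells_per_type = 60, library_size = 5000,
                               dispersion = 0, seed = 2)
  expect_true(all(cm$counts >= 0))
  expect_identical(unname(cm$labels[1]), colnames(gs$signature)[1])
  # Poisson limit: per-gene mean within 3 SE of the scaled signature mean
  q <- 2^gs$signature[, 1]
  mu <- 5000 * q / sum(q)
  obs <- rowMeans(cm$counts[, cm$labels == colnames(gs$signature)[1]])
  se <- sqrt(mu / 60)
  expect_gt(mean(abs(obs - mu) <= 3 * pmax(se, 1e-9)), 0.98)
  # doubling the library size roughly doubles column sums
  cm2 <- gen_single_cell_counts(gs, cells_per_type = 60, library_size = 10000,
                                dispersion = 0, seed = 2)
  ratio <- colSums(cm2$counts) / colSums(cm$counts)
  expect_true(all(abs(ratio - 2) < 0.2))
  expect_error(gen_single_cell_counts(gs, cells_per_type = 1), ">= 2")
})

test_that("Ct generator respects the unreliable fraction", {
  m0 <- gen_ct_array(unreliable_fraction = 0, seed = 1)
  f0 <- filter_unreliable(m0)
  expect_equal(nrow(f0$ct), nrow(m0$ct))
  expect_false(anyNA(f0$ct))
  m <- gen_ct_array(unreliable_fraction = 0.1, seed = 2)
  bad <- m$ct > m$thresholds$ct_max | m$amp < m$thresholds$amp_min
  expect_lt(abs(mean(bad) - 0.1), 0.03)
})

test_that("ligand-receptor generator reproduces a requested topology", {
  lr <- gen_lr_database(n_ligands = 6, receptors_per_ligand = c(7, 7, 7, 7, 6, 6),
                        shared_receptor_fraction = 0.2, seed = 1)
  expect_equal(nrow(lr), 40)
  expect_equal(length(unique(lr$receptor)), 32)
  expect_equal(length(unique(lr$ligand)), 6)
  expect_equal(anyDuplicated(lr), 0L)
  # no sharing: interaction count is the sum of per-ligand receptor counts
  lr0 <- gen_lr_database(n_ligands = 4, receptors_per_ligand = 3,
                         shared_receptor_fraction = 0, seed = 2)
  expect_equal(nrow(lr0), 12)
  expect_equal(length(unique(lr0$receptor)), 12)
})
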