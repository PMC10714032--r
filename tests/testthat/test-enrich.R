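# Enrichment: running-sum statistic against hand computation and
# exhaustive enumeration, hypergeometric tail, and the per-cell-type
# grid.

test_that("a set at the top of the list scores the hand-computed ES", {
  metric <- setNames(seq(10, 1), paste0("g", 1:10))
  res <- gsea_preranked(metric, c("g1", "g2"), weight = 0, n_perm = 100,
                        seed = 1)
  # two hits at ranks 1-2 with uniform decrement 1/10: max at 1 - 2/10
  expect_equal(res$es, 0.8)
  expect_setequal(res$leading_edge, c("g1", "g2"))
  expect_equal(res$size, 2)
  # a set at the bottom mirrors to a negative score
  res_lo <- gsea_preranked(metric, c("g9", "g10"), weight = 0, n_perm = 100,
                           seed = 1)
  expect_equal(res_lo$es, -0.8)
  expect_setequal(res_lo$leading_edge, c("g9", "g10"))
})

test_that("exact p-values equal exhaustive enumeration for all small universes", {
  set.seed(2)
  for (n in 4:8) {
    metric <- setNames(sort(rnorm(n, 0, 2), decreasing = TRUE),
                       paste0("g", seq_len(n)))
    for (k in 1:3) {
      positions <- sort(sample(n, k))
      set_genes <- names(metric)[positions]
      res <- gsea_preranked(metric, set_genes, weight = 1, exact = TRUE)
      oracle <- gsea_p_enumerated(positions, abs(metric)^1, n)
      expect_equal(res$es, oracle$es, tolerance = 1e-12)
      expect_equal(res$p, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("sampled permutation p-values approach the enumerated value", {
  metric <- setNames(c(5, 4, 3, 2, 1, 0.5), paste0("g", 1:6))
  # unweighted: the observed top-2 placement and its bottom-2 mirror both
  # reach |ES| = 1 - 2/6, so exactly 2 of the 15 placements are as extreme
  res_exact0 <- gsea_preranked(metric, c("g1", "g2"), weight = 0, exact = TRUE)
  expect_equal(res_exact0$p, 2 / 15)
  res_perm0 <- gsea_preranked(metric, c("g1", "g2"), weight = 0,
                              n_perm = 4000, seed = 3)
  expect_lt(abs(res_perm0$p - res_exact0$p), 0.02)
  # weighted: sampled p converges on the enumerated value too
  res_exact1 <- gsea_preranked(metric, c("g1", "g2"), exact = TRUE)
  res_perm1 <- gsea_preranked(metric, c("g1", "g2"), n_perm = 4000, seed = 4)
  expect_lt(abs(res_perm1$p - res_exact1$p), 0.03)
})

test_that("the null distribution is centred and p-values stay calibrated", {
  set.seed(4)
  metric <- setNames(rnorm(100), paste0("g", 1:100))
  # unweighted running sum: randomly placed sets score zero on average
  es_null <- vapply(1:1000, function(i) {
    set_genes <- sample(names(metric), 10)
    gsea_preranked(metric, set_genes, n_perm = 1, seed = i, weight = 0)$es
  }, numeric(1))
  expect_lt(abs(mean(es_null)), 0.05)
  expect_true(all(abs(es_null) <= 1))
  # weighted statistic: the permutation p-value stays calibrated even
  # though the signed ES itself is asymmetric under weighting
  p_null <- vapply(1:200, function(i) {
    set_genes <- sample(names(metric), 10)
    gsea_preranked(metric, set_genes, n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_lt(mean(p_null < 0.05), 0.1)
})

test_that("ES flips sign when the metric is negated and p respects the add-one bound", {
  set.seed(5)
  for (i in 1:10) {
    metric <- setNames(rnorm(40), paste0("g", 1:40))
    set_genes <- sample(names(metric), 6)
    a <- gsea_preranked(metric, set_genes, n_perm = 50, seed = i)
    b <- gsea_preranked(-metric, set_genes, n_perm = 50, seed = i)
    expect_equal(a$es, -b$es, tolerance = 1e-12)
    expect_gte(a$p, 1 / 51)
  }
  expect_error(gsea_preranked(setNames(1:4, letters[1:4]), "zzz"), "intersect")
  expect_warning(gsea_preranked(setNames(c(4, 3, 2, 1), letters[1:4]),
                                letters[1:4], n_perm = 10),
                 "entire ranked list")
})

test_that("hypergeometric over-representation matches the closed-form tail", {
  universe <- paste0("u", 1:10)
  res <- ora_hypergeom(hits = universe[1:4], gene_set = universe[1:5],
                       universe = universe)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  # zero overlap: the tail from 0 covers everything
  res0 <- ora_hypergeom(hits = universe[6:9], gene_set = universe[1:2],
                        universe = universe)
  expect_equal(res0$p, 1)
  expect_error(ora_hypergeom("a", "a", character(0)), "empty universe")
})

test_that("hypergeometric tail matches a Monte-Carlo oracle", {
  set.seed(6)
  universe <- paste0("u", 1:40)
  gene_set <- universe[1:12]
  hits <- universe[c(1:5, 20:27)]
  res <- ora_hypergeom(hits, gene_set, universe)
  draws <- replicate(20000, {
    length(intersect(sample(universe, length(hits)), gene_set))
  })
  mc <- mean(draws >= res$overlap)
  se <- sqrt(mc * (1 - mc) / 20000)
  expect_lt(abs(res$p - mc), 3 * se + 1e-6)
})

test_that("the cell-type grid recovers planted target sets", {
  gs <- gen_cell_signatures(300, 4, 30, marker_log2fc = 3, seed = 7)
  sets <- list(planted = gs$markers[[2]][1:15],
               uniform = setdiff(rownames(gs$signature),
                                 unlist(gs$markers))[1:15])
  grid <- celltype_target_enrichment(sets, gs$signature, n_perm = 500, seed = 8)
  expect_equal(nrow(grid), length(sets) * 4)
  planted <- grid[grid$set == "planted", ]
  expect_equal(planted$cell_type[which.max(planted$nes)],
               colnames(gs$signature)[2])
  expect_lt(planted$p_adj[planted$cell_type == colnames(gs$signature)[2]], 0.05)
})

test_that("uniformly expressed target sets are not called enriched", {
  false_calls <- vapply(1:20, function(s) {
    gs <- gen_cell_signatures(200, 4, 20, marker_log2fc = 3, seed = 100 + s)
    set.seed(1000 + s)
    uniform <- sample(setdiff(rownames(gs$signature), unlist(gs$markers)), 12)
    grid <- celltype_target_enrichment(list(u = uniform), gs$signature,
                                       n_perm = 200, seed = s)
    any(grid$p_adj < 0.05)
  }, logical(1))
  expect_gte(sum(!false_calls), 18)
})
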