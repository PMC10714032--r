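# Ct processing: reliability filter, normalizations, delta-delta-Ct,
# DE on inverted Ct values, and the origin classifier.

test_that("the unreliable-Ct filter applies the per-miRNA rule", {
  ct <- matrix(28, 3, 12, dimnames = list(c("miR-a", "miR-b", "miR-c"),
                                          sprintf("S%02d", 1:12)))
  amp <- matrix(1.6, 3, 12, dimnames = dimnames(ct))
  amp["miR-a", 1:4] <- 1.0        # 4 unreliable of 12: removed
  ct["miR-b", 1:3] <- 38          # 3 unreliable: kept, entries masked
  m <- ct_matrix(ct, amp, rep(c("control", "case"), each = 6))
  out <- filter_unreliable(m)
  expect_identical(rownames(out$ct), c("miR-b", "miR-c"))
  expect_true(all(is.na(out$ct["miR-b", 1:3])))
  expect_false(anyNA(out$ct["miR-c", ]))
  expect_equal(attr(out, "n_removed"), 1)
})

test_that("filter survivors match a brute-force count on generated data", {
  m <- gen_ct_array(n_mirna = 120, unreliable_fraction = 0.12, seed = 4)
  out <- filter_unreliable(m)
  bad <- is.na(m$ct) | m$ct > m$thresholds$ct_max | m$amp < m$thresholds$amp_min
  keep_brute <- rownames(m$ct)[rowSums(bad) <= m$thresholds$max_unreliable]
  expect_identical(rownames(out$ct), keep_brute)
})

test_that("normalization removes constant sample offsets and flattens RLE", {
  # samples that are exact offset copies of one profile: the offset is
  # removed exactly and all columns coincide afterwards
  base <- gen_ct_array(n_mirna = 100, n_de = 0, unreliable_fraction = 0,
                       seed = 5)
  m <- base
  offsets <- seq(-1.5, 1.5, length.out = ncol(m$ct))
  m$ct <- matrix(base$ct[, 1], nrow(base$ct), ncol(base$ct),
                 dimnames = dimnames(base$ct))
  m$ct <- sweep(m$ct, 2, offsets, "+")
  norm <- normalize_ct(m, method = "geomean")
  expect_lt(max(abs(norm$ct_matrix$ct - norm$ct_matrix$ct[, 1])), 1e-12)
  # noisy no-DE data: per-sample relative log expression centres near zero
  noisy <- gen_ct_array(n_mirna = 300, n_de = 0, unreliable_fraction = 0,
                        seed = 51)
  noisy$ct <- sweep(noisy$ct, 2, seq(-1, 1, length.out = ncol(noisy$ct)), "+")
  nn <- normalize_ct(noisy, method = "geomean")
  expect_lt(max(abs(nn$diagnostics$rle_after)), 0.05)
  # with planted offsets, low replicate noise and no DE, the three
  # strategies agree closely
  quiet <- gen_ct_array(n_mirna = 150, n_de = 0, unreliable_fraction = 0,
                        noise_sd = 0.05, seed = 52)
  quiet$ct <- sweep(quiet$ct, 2, seq(-0.3, 0.3, length.out = ncol(quiet$ct)), "+")
  n_geo <- normalize_ct(quiet, method = "geomean")
  n_rank <- normalize_ct(quiet, method = "rank_invariant")
  n_scale <- normalize_ct(quiet, method = "scale_invariant")
  expect_identical(n_rank$method, "rank_invariant")
  expect_identical(n_scale$method, "scale_invariant")
  expect_lt(max(abs(n_rank$ct_matrix$ct - n_geo$ct_matrix$ct)), 0.1)
  expect_lt(max(abs(n_scale$ct_matrix$ct - n_geo$ct_matrix$ct)), 0.1)
})

test_that("filter and normalization are insensitive to sample order", {
  m <- gen_ct_array(n_mirna = 80, unreliable_fraction = 0.05, seed = 6)
  perm <- sample(ncol(m$ct))
  mp <- m
  mp$ct <- m$ct[, perm]
  mp$amp <- m$amp[, perm]
  mp$groups <- m$groups[perm]
  a <- normalize_ct(filter_unreliable(m))$ct_matrix$ct
  b <- normalize_ct(filter_unreliable(mp))$ct_matrix$ct
  expect_equal(b, a[, perm])
})

test_that("delta-delta-Ct reproduces closed-form percent changes", {
  gr <- rep(c("control", "case"), each = 3)
  names(gr) <- sprintf("S%02d", 1:6)
  same <- setNames(rep(25, 6), names(gr))
  ref <- setNames(rep(20, 6), names(gr))
  expect_equal(ddct_percent(same, ref, gr)$percent_of_control, 100)
  # a one-cycle drop in the case group doubles expression
  target <- setNames(c(25, 25, 25, 24, 24, 24), names(gr))
  expect_equal(ddct_percent(target, ref, gr)$percent_of_control, 200)
  # randomized table against the closed form
  set.seed(7)
  t_ct <- setNames(runif(6, 22, 30), names(gr))
  r_ct <- setNames(runif(6, 18, 22), names(gr))
  res <- ddct_percent(t_ct, r_ct, gr)
  dct <- t_ct - r_ct
  ddct <- mean(dct[4:6]) - mean(dct[1:3])
  expect_equal(res$percent_of_control, 2^(-ddct) * 100, tolerance = 1e-12)
  expect_error(ddct_percent(t_ct[1:3], r_ct[1:3], gr[1:3]),
               "two non-empty sets")
})

test_that("DE on Ct values recovers planted shifts with the abundance sign convention", {
  hits <- vapply(1:5, function(s) {
    m <- gen_ct_array(n_mirna = 139, n_de = 35, de_delta_ct = -1,
                      unreliable_fraction = 0.05, seed = 40 + s)
    truth <- attr(m, "truth")
    de <- ct_de(normalize_ct(filter_unreliable(m)))
    found <- de$feature[de$p_adj < 0.05 & de$logFC > 0]
    length(intersect(found, truth$de_mirnas)) /
      length(intersect(truth$de_mirnas, de$feature))
  }, numeric(1))
  expect_gt(mean(hits), 0.8)
  # lower Ct in case group reports as positive logFC
  m <- gen_ct_array(n_mirna = 60, n_de = 10, de_delta_ct = -1, seed = 50,
                    unreliable_fraction = 0)
  de <- ct_de(normalize_ct(filter_unreliable(m)))
  truth <- attr(m, "truth")
  expect_gt(median(de$logFC[de$feature %in% truth$de_mirnas]), 0.5)
})

test_that("origin classification follows the knockout logic and is total", {
  ev <- data.frame(
    mirna = c("miR-endo", "miR-exo", "miR-ind"),
    ko_logfc = c(-1.2, 0.8, 0.1),
    ko_p = c(0.01, 0.3, 0.5),
    pri_detected = c(FALSE, FALSE, FALSE),
    pre_changed = c(FALSE, FALSE, TRUE))
  out <- classify_origin(ev)
  expect_identical(out$call, c("endogenous", "exogenous", "indeterminate"))
  # pri-form detection alone is sufficient evidence of endogenous production
  pri <- classify_origin(data.frame(mirna = "m", ko_logfc = 0.5, ko_p = 0.9,
                                    pri_detected = TRUE, pre_changed = FALSE))
  expect_identical(pri$call, "endogenous")
  # totality: every combination maps to exactly one call
  grid <- expand.grid(ko_logfc = c(-1, 0, 1), ko_p = c(0.01, 0.5),
                      pri_detected = c(TRUE, FALSE, NA),
                      pre_changed = c(TRUE, FALSE, NA))
  grid$mirna <- sprintf("m%02d", seq_len(nrow(grid)))
  calls <- classify_origin(grid)$call
  expect_true(all(calls %in% c("endogenous", "exogenous", "indeterminate")))
  expect_false(anyNA(calls))
})
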