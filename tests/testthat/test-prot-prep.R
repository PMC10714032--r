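# Preprocessing: missingness filter, left-censored imputation, variance
# stabilization.

make_missing_matrix <- function(n_feat = 500, seed = 3, rate = 0.15) {
  set.seed(seed)
  x <- matrix(rnorm(n_feat * 10, 8, 1), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                              sprintf("S%02d", 1:10)))
  x[runif(length(x)) < rate] <- NA
  ev_matrix(x, rep(c("control", "case"), each = 5))
}

test_that("missingness filter applies the per-group rule", {
  x <- matrix(8, 3, 10, dimnames = list(c("A", "B", "C"), sprintf("S%02d", 1:10)))
  x["A", 1:3] <- NA              # 3 missing in control: removed at threshold 2
  x["B", c(1, 6)] <- NA          # 1 per group: kept
  m <- ev_matrix(x, rep(c("control", "case"), each = 5))
  out <- filter_missing(m, max_missing_per_group = 2)
  expect_identical(rownames(out$values), c("B", "C"))
  # fully observed matrix passes through untouched
  full <- ev_matrix(matrix(rnorm(40), 4, 10,
                           dimnames = list(paste0("G", 1:4), sprintf("S%02d", 1:10))),
                    rep(c("control", "case"), each = 5))
  expect_identical(filter_missing(full)$values, full$values)
})

test_that("filter survivors match a brute-force per-feature count and the filter is idempotent", {
  m <- make_missing_matrix()
  out <- filter_missing(m, 2)
  keep_brute <- vapply(rownames(m$values), function(f) {
    miss_ctrl <- sum(is.na(m$values[f, 1:5]))
    miss_case <- sum(is.na(m$values[f, 6:10]))
    miss_ctrl <= 2 && miss_case <= 2
  }, logical(1))
  expect_identical(rownames(out$values), rownames(m$values)[keep_brute])
  expect_identical(filter_missing(out, 2)$values, out$values)
})

test_that("imputation draws match the left-censored Gaussian and leave observed values untouched", {
  set.seed(5)
  n_miss <- 10000
  x <- matrix(rnorm(3e4, 8, 1), 3000,
              dimnames = list(sprintf("F%04d", 1:3000), sprintf("S%02d", 1:10)))
  idx <- sample(length(x), n_miss)
  x[idx] <- NA
  m <- filter_missing(ev_matrix(x, rep(c("control", "case"), each = 5)), 4)
  pars <- impute_params(m, seed = 11)
  out <- impute_minprob(m, pars)
  expect_false(anyNA(out$values))
  imputed <- out$values[m$mask]
  expect_lt(abs(mean(imputed) - pars$mu), 3 * pars$sigma / sqrt(length(imputed)))
  expect_lt(abs(sd(imputed) / pars$sigma - 1), 0.05)
  expect_identical(out$values[!m$mask], m$values[!m$mask])
  # deterministic under a fixed seed; a complete matrix is returned unchanged
  expect_identical(impute_minprob(m, pars)$values, out$values)
  complete <- ev_matrix(x[rowSums(is.na(x)) == 0, ],
                        rep(c("control", "case"), each = 5))
  expect_identical(impute_minprob(complete)$values, complete$values)
})

test_that("imputation parameters use the observed minimum and well-observed features", {
  x <- matrix(c(5, 6, 7, 8, NA, NA, NA, 9), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), sprintf("S%02d", 1:4)))
  m <- ev_matrix(x, rep(c("control", "case"), each = 2))
  pars <- impute_params(m)
  expect_equal(pars$mu, 5)                       # 0.0-th quantile = minimum
  expect_equal(pars$sigma, sd(c(5, 6, 7, 8)))   # only feature A qualifies
  # no feature observed in more than half the samples: sigma undefined
  x2 <- matrix(c(1, NA, NA, NA, NA, 2, NA, NA), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), sprintf("S%02d", 1:4)))
  expect_error(impute_params(ev_matrix(x2, rep(c("control", "case"), each = 2))),
               "sigma undefined")
})

test_that("fits on fully observed features do not depend on the imputation seed", {
  m <- make_missing_matrix(n_feat = 200, seed = 7)
  f <- filter_missing(m)
  complete_feats <- rownames(f$values)[rowSums(f$mask) == 0]
  fit1 <- fit_two_group(impute_minprob(f, impute_params(f, seed = 1)))
  fit2 <- fit_two_group(impute_minprob(f, impute_params(f, seed = 2)))
  i <- fit1$feature %in% complete_feats
  expect_identical(fit1[i, ], fit2[i, ])
})

test_that("variance stabilization flattens the trend and preserves ranks", {
  set.seed(9)
  x <- matrix(rnorm(500 * 10, 8, 1), 500,
              dimnames = list(sprintf("F%03d", 1:500), sprintf("S%02d", 1:10)))
  m <- ev_matrix(x, rep(c("control", "case"), each = 5))
  out <- vst_normalize(m)
  expect_lt(abs(attr(out, "vst_slope")), 0.05)
  for (s in colnames(x)) {
    expect_identical(order(out$values[, s]), order(x[, s]))
  }
})

test_that("variance stabilization removes additive sample offsets", {
  set.seed(10)
  base <- rnorm(300, 8, 1)
  x <- sapply(1:6, function(s) base + rnorm(300, 0, 0.05))
  dimnames(x) <- list(sprintf("F%03d", 1:300), sprintf("S%02d", 1:6))
  x[, 4:6] <- x[, 4:6] + 3   # gross additive shift in the case samples
  m <- ev_matrix(x, rep(c("control", "case"), each = 3))
  out <- vst_normalize(m)
  meds <- apply(out$values, 2, median)
  expect_lt(max(meds) - min(meds), 0.05)
})

test_that("a constant sample is a calibration error and missing values are rejected", {
  x <- matrix(rnorm(40, 8, 1), 10,
              dimnames = list(paste0("F", 1:10), paste0("S", 1:4)))
  x[, 2] <- 5
  expect_error(vst_normalize(ev_matrix(x, rep(c("control", "case"), each = 2))),
               "calibration error")
  x2 <- matrix(rnorm(40, 8, 1), 10,
               dimnames = list(paste0("F", 1:10), paste0("S", 1:4)))
  x2[1, 1] <- NA
  expect_error(vst_normalize(ev_matrix(x2, rep(c("control", "case"), each = 2))),
               "impute")
})

test_that("provenance records the fixed pipeline order", {
  m <- make_missing_matrix(n_feat = 100, seed = 12)
  out <- vst_normalize(impute_minprob(filter_missing(m)))
  expect_identical(out$provenance, c("log2", "filter", "impute", "vst"))
})
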