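# Independent oracles used to cross-check the package's implementations.
# These are deliberately written from first principles, sharing no code
# with the package internals they verify.

# Non-negative least squares by projected gradient with diminishing
# step size: minimize ||A x - b||^2 subject to x >= 0.
nnls_projgrad <- function(A, b, iters = 20000) {
  x <- rep(0, ncol(A))
  L <- 2 * norm(crossprod(A), "2")    # Lipschitz constant of the gradient
  for (i in seq_len(iters)) {
    g <- 2 * crossprod(A, A %*% x - b)
    x_new <- pmax(x - g / L, 0)
    if (max(abs(x_new - x)) < 1e-12) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

# Enrichment score computed step by step: walk the ranked list, add the
# normalized hit weight at hits, subtract 1/N everywhere, track the
# extreme deviation.
es_stepwise <- function(hit_positions, weights_full, n) {
  wts <- unname(weights_full[hit_positions])
  if (sum(wts) <= 0) wts <- rep(1, length(hit_positions))
  wts <- wts / sum(wts)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_positions) run <- run + wts[which(hit_positions == i)]
    run <- run - 1 / n
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exhaustive permutation p-value: enumerate every placement of k hits in
# an n-long list and count |ES| at least as extreme as observed.
gsea_p_enumerated <- function(observed_positions, weights_full, n) {
  k <- length(observed_positions)
  es_obs <- es_stepwise(observed_positions, weights_full, n)
  placements <- combn(n, k)
  hits_ge <- 0
  for (j in seq_len(ncol(placements))) {
    if (abs(es_stepwise(placements[, j], weights_full, n)) >=
        abs(es_obs) - 1e-12) {
      hits_ge <- hits_ge + 1
    }
  }
  list(es = es_obs, p = hits_ge / ncol(placements))
}

# Benjamini-Hochberg by the textbook definition: order p ascending,
# multiply by m/i, enforce monotonicity from the largest rank down.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# A small complete intensity matrix with planted group effects, used by
# several suites.
make_toy_matrix <- function(n_feat = 120, n_per_group = 5, effect = 1.5,
                            n_de = 12, sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_feat * 2 * n_per_group, 8, sd), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                              sprintf("S%02d", seq_len(2 * n_per_group))))
  gr <- rep(c("control", "case"), each = n_per_group)
  if (n_de > 0) x[seq_len(n_de), gr == "case"] <- x[seq_len(n_de), gr == "case"] + effect
  list(x = x, groups = setNames(gr, colnames(x)), de = rownames(x)[seq_len(n_de)])
}
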