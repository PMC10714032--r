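# Cell-of-origin deconvolution of EV cargo by linear nu-support-vector
# regression on [0,1]-scaled matrices, CIBERSORT-style: fit over a grid
# of nu values, keep the fit with the lowest reconstruction RMSE, clamp
# negative coefficients and renormalize to fractions.

#' Deconvolution configuration
#'
#' @param nu_grid nu values for the nu-SVR (all in (0, 1]).
#' @param scaling `"signature"` (default) divides both matrices, per
#'   feature, by the signature's maximum (after rescaling each mixture
#'   sample to the signature's overall mean): one common multiplicative
#'   map per feature, which bounds the signature to `[0, 1]` and
#'   preserves the convex mixing equation exactly; `"separate"` min-max
#'   scales each matrix on its own.
#' @param space `"linear"` (default) deconvolves 2^x intensities, where
#'   mixing of cell-type contributions is additive; `"log2"` uses the
#'   values as they are.
#' @param polish refine the selected fit by non-negative least squares on
#'   the SVR-selected support (recommended; gives exact recovery on
#'   noise-free mixtures).
#' @param min_shared minimum number of shared features required.
#' @return list of class `decon_config`.
#' @export
decon_config <- function(nu_grid = c(0.25, 0.5, 0.75),
                         scaling = c("signature", "separate"),
                         space = c("linear", "log2"),
                         polish = TRUE, min_shared = 50) {
  stopifnot(all(nu_grid > 0 & nu_grid <= 1))
  structure(list(nu_grid = nu_grid, scaling = match.arg(scaling),
                 space = match.arg(space), polish = polish,
                 min_shared = min_shared),
            class = "decon_config")
}

# Scale a signature matrix and conformal mixture matrix per cfg.
#
# "signature" mode divides both matrices (linear space) by the
# signature's per-feature maximum -- an offset-free map bounding the
# signature rows to [0, 1]. Unlike subtracting a per-feature minimum,
# pure division preserves the convex mixing equation m = S p exactly,
# so noise-free mixtures remain exactly invertible; each mixture column
# is first rescaled to the signature's overall mean so cross-platform
# unit differences (e.g. CPM vs raw intensity) cancel.
#' @noRd
decon_scale <- function(sig, mix, cfg) {
  if (cfg$space == "linear") {
    sig <- 2^sig
    mix <- 2^mix
  }
  if (cfg$scaling == "signature") {
    mix <- sweep(mix, 2, colMeans(mix), "/") * mean(sig)
    r <- apply(sig, 1, max)
    r[r <= 0] <- 1
    list(sig = sig / r, mix = mix / r)
  } else {
    list(sig = unclass(minmax_scale(sig)), mix = unclass(minmax_scale(mix)))
  }
}

# Core solver on already-scaled inputs.
#' @noRd
svr_fractions <- function(y, S, cfg) {
  best <- NULL
  for (nu in cfg$nu_grid) {
    fit <- e1071::svm(x = S, y = y, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    rmse <- sqrt(mean((stats::predict(fit, S) - y)^2))
    if (is.null(best) || rmse < best$rmse) best <- list(w = w, rmse = rmse, nu = nu)
  }
  w <- pmax(best$w, 0)
  if (sum(w) <= 0) stop2("all deconvolution coefficients are non-positive; ",
                         "proportions undefined")
  if (cfg$polish) {
    sup <- which(w > 1e-8 * max(w))
    nn <- pracma::lsqnonneg(S[, sup, drop = FALSE], y)
    if (sum(nn$x) > 0) {
      w2 <- numeric(length(w))
      w2[sup] <- nn$x
      rmse2 <- sqrt(mean((S %*% w2 - y)^2))
      if (rmse2 <= best$rmse + 1e-12) {
        w <- w2
        best$rmse <- rmse2
      }
    }
  }
  p <- w / sum(w)
  names(p) <- colnames(S)
  list(proportions = p, rmse = best$rmse, nu = best$nu)
}

#' Deconvolve a single mixture profile
#'
#' Fits a linear nu-support-vector regression of the scaled mixture on
#' the scaled signature columns for each nu in the grid, keeps the fit
#' with the lowest reconstruction RMSE, clamps negative coefficients to
#' zero, optionally polishes by non-negative least squares on the
#' selected support, and normalizes to fractions summing to 1.
#'
#' @param mixture named numeric vector of scaled feature values.
#' @param sig scaled signature matrix (features x cell types) sharing the
#'   mixture's feature universe.
#' @param cfg a [decon_config()]; `scaling`/`space` are *not* applied here
#'   (inputs are taken as already scaled).
#' @return list with `proportions` (named, non-negative, summing to 1),
#'   `rmse` and the selected `nu`.
#' @export
deconvolve_sample <- function(mixture, sig, cfg = decon_config()) {
  sig <- as.matrix(sig)
  if (!is.null(names(mixture))) {
    shared <- intersect(rownames(sig), names(mixture))
    if (length(shared) < cfg$min_shared) {
      stop2("only ", length(shared), " shared features; need >= ", cfg$min_shared)
    }
    mixture <- mixture[shared]
    sig <- sig[shared, , drop = FALSE]
  } else if (length(mixture) != nrow(sig)) {
    stop2("unnamed mixture must match the signature's feature count")
  }
  svr_fractions(as.numeric(mixture), sig, cfg)
}

#' Deconvolve a cohort and test group shifts in cell-type contributions
#'
#' Scales the intensity matrix and signature per `cfg`, deconvolves every
#' sample, then compares each cell type's per-sample fractions between
#' the two groups with a two-sided Welch t test and Benjamini-Hochberg
#' adjustment. Group means are also reported as percentages.
#'
#' @param m an [ev_matrix()] (complete; typically filtered and imputed —
#'   deconvolution uses the imputed matrix, not the variance-stabilized
#'   one, because a monotone nonlinear transform distorts additive
#'   mixing of cell-type contributions).
#' @param sig log2-scale signature matrix (genes x cell types).
#' @param cfg a [decon_config()].
#' @return list of class `ev_decon` with `proportions` (samples x types),
#'   `rmse`, `nu` (per sample), and `summary` (per type: group means as
#'   fractions and percentages, Welch p, BH-adjusted p).
#' @export
deconvolve_cohort <- function(m, sig, cfg = decon_config()) {
  stopifnot(inherits(m, "ev_matrix"))
  if (any(m$mask)) stop2("matrix has missing values; run impute_minprob first")
  sig <- as.matrix(sig)
  shared <- intersect(rownames(sig), rownames(m$values))
  if (length(shared) < cfg$min_shared) {
    stop2("only ", length(shared), " features shared between matrix and ",
          "signature; need >= ", cfg$min_shared)
  }
  sc <- decon_scale(sig[shared, , drop = FALSE],
                    m$values[shared, , drop = FALSE], cfg)
  samples <- colnames(m$values)
  res <- lapply(samples, function(s) svr_fractions(sc$mix[, s], sc$sig, cfg))
  P <- do.call(rbind, lapply(res, `[[`, "proportions"))
  rownames(P) <- samples
  lv <- group_levels(m$groups)
  ctrl <- m$groups == lv[1]
  summ <- do.call(rbind, lapply(colnames(P), function(k) {
    a <- P[ctrl, k]
    b <- P[!ctrl, k]
    p <- tryCatch(stats::t.test(b, a)$p.value, error = function(e) NA_real_)
    data.frame(cell_type = k, mean_control = mean(a), mean_case = mean(b),
               pct_control = 100 * mean(a), pct_case = 100 * mean(b),
               p = p, stringsAsFactors = FALSE)
  }))
  summ$p_adj <- stats::p.adjust(summ$p, method = "BH")
  structure(list(proportions = P,
                 rmse = vapply(res, `[[`, numeric(1), "rmse"),
                 nu = vapply(res, `[[`, numeric(1), "nu"),
                 summary = summ, groups = m$groups, config = cfg),
            class = "ev_decon")
}

#' @export
#' @method print ev_decon
print.ev_decon <- function(x, ...) {
  cat(sprintf("ev_decon: %d samples x %d cell types\n",
              nrow(x$proportions), ncol(x$proportions)))
  print(x$summary, digits = 3)
  invisible(x)
}
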