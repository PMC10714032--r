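# Proteomics preprocessing: log2 intensity container, group-wise
# missingness filter, left-censored Gaussian imputation, variance
# stabilization.

#' Log2 intensity matrix with group labels
#'
#' The central container for proteomics (and Ct-derived) expression data:
#' a features x samples numeric matrix of log2 intensities with `NA` at
#' missing entries, a two-group sample assignment, and a provenance trail
#' recording which preprocessing steps have been applied.
#'
#' @param values numeric matrix (features x samples), log2 scale, `NA` for
#'   missing entries; must have row and column names.
#' @param groups character vector mapping each sample to one of exactly two
#'   group labels (named by sample, or in column order).
#' @param provenance character vector of completed steps (internal).
#' @return object of class `ev_matrix` with elements `values`, `groups`,
#'   `mask` (logical, `TRUE` = missing) and `provenance`.
#' @export
ev_matrix <- function(values, groups, provenance = "log2") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop2("values must have feature row names")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  groups <- check_groups(groups, colnames(values))
  structure(list(values = values, groups = groups, mask = is.na(values),
                 provenance = provenance),
            class = "ev_matrix")
}

#' @export
#' @method print ev_matrix
print.ev_matrix <- function(x, ...) {
  cat(sprintf("ev_matrix: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
#' @method dim ev_matrix
dim.ev_matrix <- function(x) dim(x$values)

#' Remove features with too many missing values in any group
#'
#' A feature is kept only if its missing count is at most
#' `max_missing_per_group` in *every* group. With the default of 2 and a
#' 5-vs-5 design this is the rule "proteins with more than two missing
#' values in one experimental group are removed". Feature order is
#' preserved and the operation is idempotent.
#'
#' @param m an [ev_matrix()].
#' @param max_missing_per_group maximum tolerated missing entries per group.
#' @return the filtered [ev_matrix()] (provenance gains `"filter"`).
#' @export
filter_missing <- function(m, max_missing_per_group = 2) {
  stopifnot(inherits(m, "ev_matrix"), max_missing_per_group >= 0)
  lv <- group_levels(m$groups)
  keep <- rep(TRUE, nrow(m$values))
  for (g in lv) {
    keep <- keep & rowSums(m$mask[, m$groups == g, drop = FALSE]) <= max_missing_per_group
  }
  if (!any(keep)) warning("no features survive the missingness filter")
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$mask <- m$mask[keep, , drop = FALSE]
  if (!"filter" %in% out$provenance) out$provenance <- c(out$provenance, "filter")
  out
}

#' Left-censoring imputation parameters
#'
#' mu is the 0.0-th quantile (the minimum) of all observed log2
#' intensities; sigma is the median of per-feature standard deviations
#' among features observed in more than half of the samples. Imputation
#' then draws missing entries from Gaussian(mu, sigma), placing them at
#' the low end of the intensity distribution where left-censored values
#' are expected to lie.
#'
#' @param m an [ev_matrix()].
#' @param seed integer seed used by [impute_minprob()].
#' @return object of class `impute_params` with fields `mu`, `sigma`, `seed`.
#' @export
impute_params <- function(m, seed = 1L) {
  stopifnot(inherits(m, "ev_matrix"))
  obs <- m$values[!m$mask]
  if (!length(obs)) stop2("no observed values to estimate imputation parameters")
  n_obs <- rowSums(!m$mask)
  well <- n_obs > ncol(m$values) / 2
  if (!any(well)) {
    stop2("sigma undefined: no feature is observed in more than half of the samples")
  }
  sds <- apply(m$values[well, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  structure(list(mu = min(obs), sigma = stats::median(sds, na.rm = TRUE),
                 seed = as.integer(seed)),
            class = "impute_params")
}

#' Impute missing intensities from a left-censored Gaussian
#'
#' Every missing entry is replaced by an independent draw from
#' Gaussian(`params$mu`, `params$sigma`); observed entries are untouched.
#' Draws are not truncated (they may fall below mu). The pre-imputation
#' mask is retained in `mask_original` as provenance.
#'
#' @param m an [ev_matrix()] (normally after [filter_missing()]).
#' @param params an [impute_params()] object; computed from `m` if omitted.
#' @return a complete [ev_matrix()] (provenance gains `"impute"`).
#' @export
impute_minprob <- function(m, params = impute_params(m)) {
  stopifnot(inherits(m, "ev_matrix"), inherits(params, "impute_params"))
  out <- m
  n_miss <- sum(m$mask)
  if (n_miss > 0) {
    draws <- with_seed(params$seed,
                       stats::rnorm(n_miss, params$mu, params$sigma))
    out$values[out$mask] <- draws
  }
  out$mask_original <- m$mask
  out$mask <- matrix(FALSE, nrow(m$values), ncol(m$values),
                     dimnames = dimnames(m$values))
  out$impute_params <- params
  if (!"impute" %in% out$provenance) out$provenance <- c(out$provenance, "impute")
  out
}

#' Variance-stabilizing normalization
#'
#' Two steps. (1) Per-sample affine calibration: each sample is
#' median-centred and MAD-scaled to the pooled reference, removing
#' sample-wise shifts and scale differences. (2) A monotone
#' trend-flattening transform: the SD-versus-mean trend across features
#' is estimated by lowess and the values are passed through the
#' integral of 1/trend, which is strictly increasing and flattens the
#' mean-variance relationship; the result is re-calibrated to the input's
#' median/MAD so the scale stays interpretable. Within each sample the
#' transform preserves rank order.
#'
#' @param m a complete [ev_matrix()] (no missing entries).
#' @param slope_tol warn if the residual |slope| of the lowess SD-vs-mean
#'   trend exceeds this value.
#' @param lowess_f lowess smoother span.
#' @return the transformed [ev_matrix()] (provenance gains `"vst"`);
#'   attribute `"vst_slope"` records the residual trend slope.
#' @export
vst_normalize <- function(m, slope_tol = 0.05, lowess_f = 2/3) {
  stopifnot(inherits(m, "ev_matrix"))
  if (any(m$mask)) stop2("vst_normalize requires a complete matrix; impute first")
  x <- m$values
  pooled_med <- stats::median(x)
  pooled_mad <- stats::mad(x)
  meds <- apply(x, 2, stats::median)
  mads <- apply(x, 2, stats::mad)
  if (any(mads < .Machine$double.eps)) {
    stop2("calibration error: sample(s) with zero spread: ",
          paste(colnames(x)[mads < .Machine$double.eps], collapse = ", "))
  }
  xc <- sweep(sweep(x, 2, meds), 2, mads, "/") * pooled_mad + pooled_med

  mu <- rowMeans(xc)
  sd_f <- apply(xc, 1, stats::sd)
  ok <- is.finite(mu) & is.finite(sd_f)
  lo <- stats::lowess(mu[ok], sd_f[ok], f = lowess_f)
  trend <- pmax(lo$y, 1e-3 * stats::median(lo$y[lo$y > 0], na.rm = TRUE))
  # h(x) = integral of 1/trend: strictly increasing, flattens SD-vs-mean
  h_y <- cumsum(c(0, diff(lo$x) * (1 / trend[-1] + 1 / trend[-length(trend)]) / 2))
  grid_x <- lo$x
  dup <- duplicated(grid_x)
  grid_x <- grid_x[!dup]
  h_y <- h_y[!dup]
  if (length(grid_x) < 2) stop2("calibration error: degenerate mean grid")
  slope_lo <- (h_y[2] - h_y[1]) / max(grid_x[2] - grid_x[1], 1e-12)
  slope_hi <- (h_y[length(h_y)] - h_y[length(h_y) - 1]) /
    max(grid_x[length(grid_x)] - grid_x[length(grid_x) - 1], 1e-12)
  apply_h <- function(v) {
    out <- stats::approx(grid_x, h_y, xout = v, rule = 2)$y
    lowi <- v < grid_x[1]
    highi <- v > grid_x[length(grid_x)]
    out[lowi] <- h_y[1] + (v[lowi] - grid_x[1]) * slope_lo
    out[highi] <- h_y[length(h_y)] + (v[highi] - grid_x[length(grid_x)]) * slope_hi
    out
  }
  xt <- matrix(apply_h(as.vector(xc)), nrow(xc), ncol(xc), dimnames = dimnames(xc))
  # re-calibrate to the input scale
  tmad <- stats::mad(xt)
  if (tmad < .Machine$double.eps) tmad <- stats::sd(xt)
  xt <- (xt - stats::median(xt)) / tmad * pooled_mad + pooled_med

  mu2 <- rowMeans(xt)
  sd2 <- apply(xt, 1, stats::sd)
  lo2 <- stats::lowess(mu2, sd2, f = lowess_f)
  slope <- if (stats::sd(lo2$x) > 0) {
    stats::coef(stats::lm(lo2$y ~ lo2$x))[2]
  } else 0
  if (is.finite(slope) && abs(slope) > slope_tol) {
    warning(sprintf("residual SD-vs-mean trend slope %.3f exceeds tolerance %.3f",
                    slope, slope_tol))
  }
  out <- m
  out$values <- xt
  if (!"vst" %in% out$provenance) out$provenance <- c(out$provenance, "vst")
  attr(out, "vst_slope") <- unname(slope)
  out
}
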