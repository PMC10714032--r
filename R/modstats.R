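# Two-group differential expression with empirical-Bayes variance
# moderation. The per-feature fit is an ordinary pooled two-sample linear
# model; moderation shrinks the residual variances toward a prior
# estimated by the method of moments on log variances, and the moderated
# t is referred to a t distribution with augmented degrees of freedom.

#' Per-feature two-group linear fit
#'
#' For each feature computes the log2 fold change (case minus control),
#' the pooled within-group residual variance and its degrees of freedom.
#'
#' @param m an [ev_matrix()] (complete, unless `na.rm = TRUE`) or a plain
#'   numeric matrix with `groups` supplied.
#' @param groups two-group sample assignment (taken from `m` if it is an
#'   `ev_matrix`).
#' @param na.rm if `TRUE`, group means/variances use available entries per
#'   feature and the residual df shrinks accordingly (used for Ct data
#'   where isolated unreliable entries remain missing).
#' @return data.frame of class `ev_fits` with columns `feature`, `logFC`,
#'   `mean_control`, `mean_case`, `s2`, `df`, `n_control`, `n_case`; the
#'   group labels are attached as attributes.
#' @export
fit_two_group <- function(m, groups = NULL, na.rm = FALSE) {
  if (inherits(m, "ev_matrix")) {
    x <- m$values
    groups <- m$groups
  } else {
    x <- as.matrix(m)
    groups <- check_groups(groups, colnames(x))
  }
  if (!na.rm && anyNA(x)) {
    stop2("matrix contains missing values; impute first or use na.rm = TRUE")
  }
  lv <- group_levels(groups)
  x1 <- x[, groups == lv[1], drop = FALSE]   # control / reference
  x2 <- x[, groups == lv[2], drop = FALSE]   # case
  if (ncol(x1) < 2 || ncol(x2) < 2) stop2("each group needs at least 2 samples")
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  if (any(n1 < 2 | n2 < 2)) {
    stop2("feature(s) with fewer than 2 observed samples in a group; filter first")
  }
  m1 <- rowMeans(x1, na.rm = na.rm)
  m2 <- rowMeans(x2, na.rm = na.rm)
  ss1 <- rowSums((x1 - m1)^2, na.rm = na.rm)
  ss2 <- rowSums((x2 - m2)^2, na.rm = na.rm)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  out <- data.frame(feature = rownames(x), logFC = m2 - m1,
                    mean_control = m1, mean_case = m2,
                    s2 = s2, df = df, n_control = n1, n_case = n2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_levels") <- lv
  class(out) <- c("ev_fits", "data.frame")
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
#' @noRd
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok & !is.na(y) & y <= 0] <- Inf
  if (any(ok)) {
    x <- 0.5 + 1 / y[ok]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[ok]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[ok] <- x
  }
  out
}

# Method-of-moments prior on log variances: matches the mean and variance
# of log(s2) to those of a scaled F distribution, using digamma/trigamma
# identities; returns the prior df d0 and prior variance s0_sq.
#' @noRd
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = stats::median(s2[s2 > 0])))
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion in log variances: variances are exchangeable
    # and the prior collapses to their mean
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderation of two-group fits
#'
#' Shrinks each feature's residual variance toward a prior:
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`. The moderated t is
#' `logFC / sqrt(s2_post * (1/n1 + 1/n2))` with `d0 + df` degrees of
#' freedom. When `d0`/`s0_sq` are not supplied they are estimated by the
#' method of moments on log variances. `d0 = 0` reduces exactly to the
#' ordinary pooled two-sample t; `d0 = Inf` gives a z-like statistic with
#' variance fixed at `s0_sq`. Benjamini-Hochberg adjustment is applied
#' across all tested features.
#'
#' @param fits output of [fit_two_group()].
#' @param d0,s0_sq optional prior degrees of freedom and prior variance.
#' @return data.frame of class `ev_de` with columns `feature`, `logFC`,
#'   `t`, `p`, `p_adj`, `mean_control`, `mean_case`, `s2`, `s2_post`,
#'   `df_total`; attributes `d0` and `s0_sq` record the prior. Features
#'   with zero posterior variance get infinite t and p = 0, and are
#'   flagged in the logical column `infinite_t`.
#' @export
ebayes_moderate <- function(fits, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(fits, "ev_fits"))
  if (nrow(fits) < 10 && is.null(d0)) {
    warning("fewer than 10 features: prior estimation is unstable")
  }
  if (is.null(d0) || is.null(s0_sq)) {
    if (all(fits$s2 == 0)) {
      warning("all residual variances are zero; moderation degenerates")
      pr <- list(d0 = 0, s0_sq = 1)
    } else {
      pr <- estimate_prior(fits$s2, fits$df)
    }
    d0 <- d0 %||% pr$d0
    s0_sq <- s0_sq %||% pr$s0_sq
  }
  stopifnot(d0 >= 0, s0_sq > 0)
  s2_post <- if (is.infinite(d0)) rep(s0_sq, nrow(fits)) else {
    (d0 * s0_sq + fits$df * fits$s2) / (d0 + fits$df)
  }
  se <- sqrt(s2_post * (1 / fits$n_control + 1 / fits$n_case))
  tval <- fits$logFC / se
  # the moderated t cannot carry more information than the pooled
  # residual df across all features
  df_total <- pmin(d0 + fits$df, sum(fits$df))
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(tval)),
              2 * stats::pt(-abs(tval), df = df_total))
  inf_t <- !is.finite(tval) & fits$logFC != 0
  tval[is.nan(tval)] <- 0          # 0/0: no change, no evidence
  p[is.nan(p)] <- 1
  p[inf_t] <- 0
  if (any(inf_t)) {
    warning(sum(inf_t), " feature(s) with zero posterior variance and ",
            "non-zero effect: t is infinite")
  }
  out <- data.frame(feature = fits$feature, logFC = fits$logFC,
                    t = tval, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    mean_control = fits$mean_control,
                    mean_case = fits$mean_case,
                    s2 = fits$s2, s2_post = s2_post, df_total = df_total,
                    infinite_t = inf_t,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "group_levels") <- attr(fits, "group_levels")
  class(out) <- c("ev_de", "data.frame")
  out
}

#' Moderated two-group differential expression in one call
#'
#' Convenience wrapper: [fit_two_group()] then [ebayes_moderate()].
#'
#' @inheritParams fit_two_group
#' @inheritParams ebayes_moderate
#' @return an `ev_de` data.frame, see [ebayes_moderate()].
#' @export
de_moderated <- function(m, groups = NULL, na.rm = FALSE, d0 = NULL, s0_sq = NULL) {
  ebayes_moderate(fit_two_group(m, groups = groups, na.rm = na.rm),
                  d0 = d0, s0_sq = s0_sq)
}

#' Filter and rank a differential-expression table
#'
#' Keeps features with `p < p_cut` and `|logFC| > lfc_cut` (both strict),
#' sorted by p ascending; up/down counts are attached as attributes.
#'
#' @param de an `ev_de` data.frame from [ebayes_moderate()].
#' @param p_cut,lfc_cut thresholds (raw p and absolute log2 fold change).
#' @param use_adjusted filter on `p_adj` instead of raw `p`.
#' @return the filtered, ranked `ev_de` with attributes `n_up` and `n_down`.
#' @export
top_table <- function(de, p_cut = 0.05, lfc_cut = 0, use_adjusted = FALSE) {
  stopifnot(inherits(de, "ev_de"), p_cut >= 0, lfc_cut >= 0)
  pcol <- if (use_adjusted) de$p_adj else de$p
  keep <- pcol < p_cut & abs(de$logFC) > lfc_cut
  out <- de[keep, , drop = FALSE]
  out <- out[order(out$p, -abs(out$logFC), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$logFC > 0)
  attr(out, "n_down") <- sum(out$logFC < 0)
  attr(out, "d0") <- attr(de, "d0")
  attr(out, "s0_sq") <- attr(de, "s0_sq")
  class(out) <- c("ev_de", "data.frame")
  out
}
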