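# OpenArray/qPCR Ct processing: reliability filtering on Ct ceiling and
# amplification score, three normalization strategies, delta-delta-Ct
# percent-of-control, moderated DE on inverted Ct values, and the
# endogenous-vs-exogenous miRNA origin classifier.

#' Ct matrix with amplification scores
#'
#' @param ct numeric matrix (miRNA x samples) of cycle-threshold values
#'   (`NA` allowed for undetermined wells).
#' @param amp conformal matrix of amplification quality scores.
#' @param groups two-group sample assignment.
#' @param ct_max Ct ceiling above which an entry is unreliable. No printed
#'   consensus value exists for OpenArray panels; the default 35 must be
#'   reviewed against a Ct-vs-AmpScore density plot for real data.
#' @param amp_min minimum acceptable amplification score (default 1.24;
#'   same caveat).
#' @param max_unreliable maximum unreliable entries per miRNA before the
#'   whole feature is excluded (default 3, for a 12-sample panel).
#' @return object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, amp, groups, ct_max = 35, amp_min = 1.24,
                      max_unreliable = 3) {
  ct <- as.matrix(ct)
  amp <- as.matrix(amp)
  if (!identical(dim(ct), dim(amp))) stop2("ct and amp must be conformal")
  if (any(ct[!is.na(ct)] <= 0)) stop2("observed Ct values must be positive")
  if (is.null(rownames(ct))) stop2("ct must have miRNA row names")
  if (is.null(colnames(ct))) colnames(ct) <- sprintf("S%02d", seq_len(ncol(ct)))
  dimnames(amp) <- dimnames(ct)
  groups <- check_groups(groups, colnames(ct))
  structure(list(ct = ct, amp = amp, groups = groups,
                 thresholds = list(ct_max = ct_max, amp_min = amp_min,
                                   max_unreliable = max_unreliable)),
            class = "ct_matrix")
}

#' @export
#' @method print ct_matrix
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d miRNAs x %d samples\n", nrow(x$ct), ncol(x$ct)))
  cat(sprintf("thresholds: ct_max=%.4g amp_min=%.4g max_unreliable=%d\n",
              x$thresholds$ct_max, x$thresholds$amp_min,
              x$thresholds$max_unreliable))
  invisible(x)
}

#' Remove unreliable Ct measurements and poorly measured miRNAs
#'
#' An entry is unreliable when its Ct exceeds `ct_max`, its amplification
#' score falls below `amp_min`, or it is undetermined (`NA`). miRNAs with
#' more than `max_unreliable` unreliable entries are removed entirely;
#' surviving miRNAs keep their remaining unreliable entries as `NA`.
#'
#' @param m a [ct_matrix()].
#' @return the filtered [ct_matrix()]; attributes `n_removed` and
#'   `unreliable` (logical matrix for the surviving rows) document the
#'   filtering.
#' @export
filter_unreliable <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  th <- m$thresholds
  bad <- is.na(m$ct) | m$ct > th$ct_max | m$amp < th$amp_min
  keep <- rowSums(bad) <= th$max_unreliable
  out <- m
  out$ct <- m$ct[keep, , drop = FALSE]
  out$amp <- m$amp[keep, , drop = FALSE]
  out$ct[bad[keep, , drop = FALSE]] <- NA_real_
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "unreliable") <- bad[keep, , drop = FALSE]
  out
}

# Per-sample relative log expression spread (Ct is already log-scale):
# median per sample of ct minus the feature-wise median.
#' @noRd
rle_medians <- function(ct) {
  ref <- apply(ct, 1, stats::median, na.rm = TRUE)
  apply(ct - ref, 2, stats::median, na.rm = TRUE)
}

#' Normalize Ct values across samples
#'
#' Three strategies, all operating on the log-scale Ct values directly:
#' * `geomean`: subtract each sample's mean Ct (the log-scale equivalent
#'   of dividing by the sample geometric mean) and re-centre at the
#'   global mean.
#' * `rank_invariant`: normalize to the mean Ct of features whose
#'   cross-sample rank standard deviation is at most `rank_sd_max`.
#' * `scale_invariant`: normalize to the features with cross-sample
#'   coefficient of variation at most `cv_max`.
#'
#' If no invariant feature qualifies the method falls back to `geomean`
#' with a warning. Diagnostics report the per-sample relative log
#' expression medians before and after.
#'
#' @param m a filtered [ct_matrix()].
#' @param method normalization strategy.
#' @param rank_sd_max rank-invariance band (rank SD units).
#' @param cv_max coefficient-of-variation ceiling for `scale_invariant`.
#' @return list of class `ct_norm`: the normalized `ct_matrix`, the
#'   `method` actually used, `reference_features`, and `diagnostics`
#'   (`rle_before`, `rle_after`).
#' @export
normalize_ct <- function(m, method = c("geomean", "rank_invariant",
                                       "scale_invariant"),
                         rank_sd_max = 1, cv_max = 0.02) {
  stopifnot(inherits(m, "ct_matrix"))
  method <- match.arg(method)
  ct <- m$ct
  rle_before <- rle_medians(ct)
  complete <- stats::complete.cases(ct)
  ref_feats <- NULL
  used <- method
  if (method == "rank_invariant") {
    if (sum(complete) >= 2) {
      rk <- apply(ct[complete, , drop = FALSE], 2, rank)
      rk_sd <- apply(rk, 1, stats::sd)
      ref_feats <- rownames(ct)[complete][rk_sd <= rank_sd_max]
    }
    if (length(ref_feats) == 0) {
      warning("no rank-invariant features found; falling back to geomean")
      used <- "geomean"
    }
  } else if (method == "scale_invariant") {
    if (sum(complete) >= 2) {
      cc <- ct[complete, , drop = FALSE]
      cv <- apply(cc, 1, stats::sd) / rowMeans(cc)
      ref_feats <- rownames(ct)[complete][cv <= cv_max]
    }
    if (length(ref_feats) == 0) {
      warning("no scale-invariant features found; falling back to geomean")
      used <- "geomean"
    }
  }
  if (used == "geomean") {
    samp_ref <- colMeans(ct, na.rm = TRUE)
    centre <- mean(ct, na.rm = TRUE)
  } else {
    samp_ref <- colMeans(ct[ref_feats, , drop = FALSE], na.rm = TRUE)
    centre <- mean(ct[ref_feats, ], na.rm = TRUE)
  }
  out <- m
  out$ct <- sweep(ct, 2, samp_ref) + centre
  structure(list(ct_matrix = out, method = used,
                 reference_features = ref_feats,
                 diagnostics = list(rle_before = rle_before,
                                    rle_after = rle_medians(out$ct))),
            class = "ct_norm")
}

#' Comparative Ct (delta-delta-Ct) as percent of control
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; then
#' `ddCt = mean(dCt_case) - mean(dCt_control)` and the reported value is
#' `2^(-ddCt) * 100` percent of control (a ddCt of -1 doubles expression,
#' i.e. 200%).
#'
#' @param target_ct,reference_ct named numeric vectors of Ct values for
#'   the target and the reference assay (e.g. U6), sample-matched.
#' @param groups two-group sample assignment.
#' @return list with `percent_of_control`, `ddct` and the per-group mean
#'   `dct`.
#' @export
ddct_percent <- function(target_ct, reference_ct, groups) {
  samples <- names(target_ct) %||% names(reference_ct)
  if (is.null(samples)) {
    if (length(target_ct) != length(reference_ct)) {
      stop2("target and reference must be sample-matched")
    }
    samples <- sprintf("S%02d", seq_along(target_ct))
    names(target_ct) <- names(reference_ct) <- samples
  }
  reference_ct <- reference_ct[samples]
  if (anyNA(target_ct) || anyNA(reference_ct)) {
    stop2("missing Ct values in target or reference")
  }
  groups <- check_groups(groups, samples)
  lv <- group_levels(groups)
  dct <- target_ct - reference_ct
  if (!all(lv %in% groups)) stop2("both groups must be present")
  d_ctrl <- mean(dct[groups == lv[1]])
  d_case <- mean(dct[groups == lv[2]])
  ddct <- d_case - d_ctrl
  list(percent_of_control = 2^(-ddct) * 100, ddct = ddct,
       dct_control = d_ctrl, dct_case = d_case)
}

#' Moderated differential expression on Ct values
#'
#' Runs the two-group moderated-t workflow on *inverted* Ct values
#' (lower Ct means higher expression), so reported log fold changes
#' follow the abundance convention: a Ct decrease of 1 cycle in the case
#' group appears as `logFC = +1`.
#'
#' @param x a [ct_matrix()] (typically normalized, via `ct_norm$ct_matrix`)
#'   or a `ct_norm` object.
#' @return an `ev_de` data.frame (see [ebayes_moderate()]).
#' @export
ct_de <- function(x) {
  if (inherits(x, "ct_norm")) x <- x$ct_matrix
  stopifnot(inherits(x, "ct_matrix"))
  de_moderated(-x$ct, groups = x$groups, na.rm = anyNA(x$ct))
}

#' Classify miRNA origin as endogenous or exogenous
#'
#' Applies the DICER-knockout logic: a miRNA that drops significantly
#' when the producing cell cannot mature miRNA (DICER KO) -- or whose
#' primary transcript is detected in the cell -- is endogenously
#' produced. A miRNA that rises or does not change in the KO, with no
#' detected pri-form and unchanged pre-form, must be imported
#' (exogenous). Everything else is indeterminate.
#'
#' @param evidence data.frame with columns `mirna`, `ko_logfc` (KO vs WT
#'   log2 fold change), `ko_p` (its p-value), and optionally logical
#'   `pri_detected` and `pre_changed` (`NA` treated as `FALSE`).
#' @param alpha significance level for the KO contrast.
#' @return the evidence data.frame with an added `call` column
#'   (`endogenous`, `exogenous`, `indeterminate`).
#' @export
classify_origin <- function(evidence, alpha = 0.05) {
  req <- c("mirna", "ko_logfc", "ko_p")
  if (!all(req %in% names(evidence))) {
    stop2("evidence needs columns: ", paste(req, collapse = ", "))
  }
  pri <- evidence$pri_detected %||% rep(FALSE, nrow(evidence))
  pre <- evidence$pre_changed %||% rep(FALSE, nrow(evidence))
  pri[is.na(pri)] <- FALSE
  pre[is.na(pre)] <- FALSE
  ko_down <- evidence$ko_logfc < 0 & evidence$ko_p < alpha
  call <- ifelse(ko_down | pri, "endogenous",
                 ifelse(!pri & !pre, "exogenous", "indeterminate"))
  evidence$pri_detected <- pri
  evidence$pre_changed <- pre
  evidence$call <- call
  evidence
}
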