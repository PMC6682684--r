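## Cohort-level statistics: correlations, group contrasts, channel-wise
## correlation topography with Benjamini-Hochberg FDR control, low-AUC
## outlier screening, and the RSVP trial-count sweep.

#' Pearson correlation with p-value
#'
#' Product-moment correlation and its two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, both
#'   non-constant).
#' @return Named list `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Split a cohort into high- and low-performance groups
#'
#' Sorts subjects by AUC ascending (ties broken by subject id, so the
#' split is deterministic) and returns the bottom `n_bottom` as the low
#' group and the top `n_top` as the high group.
#'
#' @param auc Named numeric vector of per-subject AUCs (names = subject
#'   ids) or a plain vector with `ids` supplied.
#' @param n_top,n_bottom Group sizes.
#' @param ids Subject ids if `auc` is unnamed.
#' @return List with character vectors `high` and `low`.
#' @export
split_groups <- function(auc, n_top = 10, n_bottom = 10, ids = names(auc)) {
  if (is.null(ids)) ids <- as.character(seq_along(auc))
  if (length(auc) < n_top + n_bottom) {
    stop("cohort smaller than n_top + n_bottom")
  }
  ord <- order(auc, ids)
  list(high = ids[ord][seq.int(length(auc) - n_top + 1, length(auc))],
       low = ids[ord][seq_len(n_bottom)])
}

#' Unpaired two-sample Student's t-test
#'
#' Pooled-variance t statistic with `n_a + n_b - 2` degrees of freedom
#' and a two-sided p-value; Welch's unequal-variance form is available
#' via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param var_equal Pool the variances (Student's test) if `TRUE`.
#' @return Named list `t`, `p`, `df`.
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, find
#' the largest k with `p_(k) <= k * q / m`; all p-values up to `p_(k)`
#' are flagged significant.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate.
#' @return Logical mask, `TRUE` where significant.
#' @export
fdr_bh <- function(pvalues, q = 0.1) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Channel-wise correlation topography
#'
#' Correlates one per-channel feature with the per-subject AUC, channel
#' by channel, and attaches Benjamini-Hochberg FDR flags at rate `q`.
#'
#' @param per_channel_feature Subjects x channels matrix (columns named
#'   by channel).
#' @param auc Per-subject outcome, same subject order.
#' @param q FDR level.
#' @return Tibble: `channel`, `r`, `p_uncorrected`, `fdr_significant`.
#' @export
correlation_topography <- function(per_channel_feature, auc, q = 0.1) {
  M <- as.matrix(per_channel_feature)
  if (nrow(M) != length(auc)) stop("subject mismatch")
  if (any(apply(M, 2, stats::sd) == 0)) stop("constant channel feature")
  res <- apply(M, 2, function(col) unlist(pearson(col, auc)[c("r", "p")]))
  tibble::tibble(
    channel = colnames(M),
    r = unname(res["r", ]),
    p_uncorrected = unname(res["p", ]),
    fdr_significant = fdr_bh(unname(res["p", ]), q = q))
}

#' Flag low-performance outliers
#'
#' Flags subjects whose AUC lies below `mean - k * SD` (one-sided low,
#' matching the screening of disengaged subjects); a two-sided variant
#' also flags values above `mean + k * SD`.
#'
#' @param auc Per-subject AUCs (named, or `ids` supplied).
#' @param k SD multiplier.
#' @param two_sided Also flag high outliers.
#' @param ids Subject ids if `auc` is unnamed.
#' @return Character vector of flagged subject ids.
#' @export
detect_outliers <- function(auc, k = 2.5, two_sided = FALSE,
                            ids = names(auc)) {
  if (is.null(ids)) ids <- as.character(seq_along(auc))
  if (length(auc) < 3) stop("need at least 3 subjects")
  s <- stats::sd(auc)
  if (s == 0) return(character(0))
  low <- auc < mean(auc) - k * s
  if (two_sided) low <- low | auc > mean(auc) + k * s
  ids[low]
}

#' Trial-count sweep of feature-AUC correlations
#'
#' Recomputes every subject's RSVP features from trials 1..N for each N
#' in `n_range` (subjects with fewer retained trials use all remaining)
#' and correlates each feature with the speller AUC; optionally also
#' evaluates the two multi-feature predictors by leave-one-subject-out
#' cross-validation at each N.
#'
#' @param series_list Per-subject list of [trial_peak_series()] tibbles.
#' @param behavior_list Per-subject list of behavior logs.
#' @param auc Per-subject AUCs, same order.
#' @param n_range Trial counts to evaluate (minimum 5, since the trial
#'   variations need at least five trials).
#' @param include_models Also evaluate the regular and stepwise
#'   multi-feature predictors at each N.
#' @return Tibble: `n_trials`, `predictor`, `r`, `p`.
#' @export
trial_sweep <- function(series_list, behavior_list, auc, n_range = 5:40,
                        include_models = TRUE) {
  if (any(n_range < 5)) stop("n_range must be >= 5")
  n_sub <- length(series_list)
  stopifnot(length(behavior_list) == n_sub, length(auc) == n_sub)
  out <- list()
  for (N in n_range) {
    feats <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
      subject_features(NULL, behavior_list[[i]], first_n = N,
                       series = series_list[[i]])
    }))
    X <- as.matrix(feats[, FEATURE_COLS])
    for (f in FEATURE_COLS) {
      ct <- if (stats::sd(X[, f]) == 0) list(r = NA_real_, p = NA_real_)
            else pearson(X[, f], auc)
      out[[length(out) + 1]] <- tibble::tibble(
        n_trials = N, predictor = f, r = ct$r, p = ct$p)
    }
    if (include_models) {
      for (kind in c("multiple", "stepwise")) {
        ev <- tryCatch(loso_evaluate(X, auc, kind), error = function(e)
          list(r = NA_real_, p = NA_real_))
        out[[length(out) + 1]] <- tibble::tibble(
          n_trials = N,
          predictor = if (kind == "multiple") "multi_regular"
                      else "multi_stepwise",
          r = ev$r, p = ev$p)
      }
    }
  }
  do.call(rbind, out)
}
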