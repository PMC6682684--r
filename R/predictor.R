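## Single- and multi-feature regression predictors of speller AUC,
## evaluated in-sample and by leave-one-subject-out cross-validation.

FEATURE_COLS <- c("t1_percent", "p300_amplitude", "p300_latency",
                  "amp_trial_sd", "lat_trial_sd")

#' Z-score features using training rows only
#'
#' Standardizes every column with the mean and sample SD computed from
#' `fit_rows` alone and applies the transform to all rows, so held-out
#' subjects never leak into the standardization.
#'
#' @param features Numeric matrix or data frame of features.
#' @param fit_rows Row indices used to estimate means and SDs; default
#'   all rows.
#' @return List with `scaled` (matrix), `center`, `scale`.
#' @export
zscore <- function(features, fit_rows = seq_len(nrow(features))) {
  X <- as.matrix(features)
  if (length(fit_rows) < 2) stop("need at least 2 fitting rows")
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sdv <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance feature among fitting rows: ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  }
  list(scaled = sweep(sweep(X, 2, mu), 2, sdv, "/"),
       center = mu, scale = sdv)
}

.regression_stats <- function(fit, y) {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  r2 <- sm$r.squared
  tibble::tibble(
    r = NA_real_,                              # filled by callers
    p = if (!is.null(fstat))
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    else NA_real_,
    F = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    R2 = r2,
    MSE = mean(stats::residuals(fit)^2) * 100^2)
}

#' Single-feature linear predictor
#'
#' Ordinary least-squares regression of the outcome on one feature, with
#' the standard simple-regression statistics (F equals the squared slope
#' t-statistic; in-sample R-squared equals r-squared). The in-sample MSE
#' is reported on the x100 AUC scale.
#'
#' @param x Feature values (one per subject).
#' @param y Outcome (speller AUC, 0-1 scale).
#' @return List with `model` (class `predictor_model`) and `stats`
#'   (one-row tibble: r, p, F, R2, MSE).
#' @export
fit_single <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 subjects")
  if (stats::sd(x) == 0) stop("zero-variance feature")
  fit <- stats::lm(y ~ x)
  st <- .regression_stats(fit, y)
  st$r <- stats::cor(x, y)
  model <- structure(
    list(kind = "single", weights = stats::coef(fit)[-1],
         intercept = unname(stats::coef(fit)[1]), z_params = NULL),
    class = "predictor_model")
  list(model = model, stats = st)
}

#' Multi-feature (regular) linear predictor
#'
#' Least-squares fit of the outcome on all five z-scored RSVP features
#' plus an intercept; the overall F statistic has (5, n - 6) degrees of
#' freedom.
#'
#' @param X Matrix/data frame of the five features (already z-scored; see
#'   [zscore()]).
#' @param y Outcome.
#' @return List with `model` and `stats` as in [fit_single()].
#' @export
fit_multiple <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= ncol(X) + 1) stop("need n > number of features + 1")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("rank-deficient design")
  df <- as.data.frame(X)
  df$y <- y
  fit <- stats::lm(y ~ ., data = df)
  st <- .regression_stats(fit, y)
  st$r <- stats::cor(stats::fitted(fit), y)
  model <- structure(
    list(kind = "multiple", weights = stats::coef(fit)[-1],
         intercept = unname(stats::coef(fit)[1]), z_params = NULL),
    class = "predictor_model")
  list(model = model, stats = st)
}

#' Stepwise multi-feature predictor
#'
#' Forward/backward p-value selection over the five features (no feature
#' cap), as in [swlda_fit()] but with regression defaults
#' `p_enter = 0.05`, `p_remove = 0.10`; the returned model contains only
#' the surviving features. If none qualifies, an intercept-only model is
#' returned whose predictions are the training mean.
#'
#' @param X Matrix/data frame of the five (z-scored) features.
#' @param y Outcome.
#' @param p_enter,p_remove Entry/removal thresholds.
#' @return List with `model` and `stats`; `stats` are those of the OLS
#'   fit on the selected subset.
#' @export
fit_stepwise <- function(X, y, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(X)
  n <- nrow(X)
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx)
  yc <- y - mean(y)
  S <- .stepwise_select(crossprod(Xc), drop(crossprod(Xc, yc)),
                        sum(yc^2), n, p_enter, p_remove,
                        max_features = ncol(X))
  weights <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(S) == 0) {
    model <- structure(
      list(kind = "stepwise", weights = weights, intercept = mean(y),
           selected = integer(0), z_params = NULL),
      class = "predictor_model")
    st <- tibble::tibble(r = NA_real_, p = NA_real_, F = NA_real_,
                         R2 = 0, MSE = mean((y - mean(y))^2) * 100^2)
    return(list(model = model, stats = st))
  }
  df <- as.data.frame(X[, S, drop = FALSE])
  df$y <- y
  fit <- stats::lm(y ~ ., data = df)
  st <- .regression_stats(fit, y)
  st$r <- stats::cor(stats::fitted(fit), y)
  weights[S] <- stats::coef(fit)[-1]
  model <- structure(
    list(kind = "stepwise", weights = weights,
         intercept = unname(stats::coef(fit)[1]), selected = S,
         z_params = NULL),
    class = "predictor_model")
  list(model = model, stats = st)
}

#' Predict from a fitted predictor model
#'
#' @param object A `predictor_model`.
#' @param newdata Feature matrix on the same scale the model was fit on.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.predictor_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  w <- object$weights
  if (object$kind == "single") {
    return(drop(X[, 1] * w[1]) + object$intercept)
  }
  if (all(w == 0)) return(rep(object$intercept, nrow(X)))
  used <- names(w)[w != 0]
  if (!is.null(colnames(X)) && all(used %in% colnames(X))) {
    drop(X[, used, drop = FALSE] %*% w[used]) + object$intercept
  } else {
    drop(X %*% w) + object$intercept
  }
}

#' Leave-one-subject-out evaluation of a predictor
#'
#' For each subject, z-scores the features and fits the chosen predictor
#' on all other subjects, then predicts the held-out subject. Reports the
#' Pearson correlation between predictions and actual outcomes, its
#' two-sided p-value from the t transform with n - 2 degrees of freedom,
#' and the mean squared error with both series multiplied by 100.
#'
#' @param X Matrix/data frame of the five raw (unscaled) features.
#' @param y Outcome per subject (AUC, 0-1 scale).
#' @param model_kind `"single"`, `"multiple"` or `"stepwise"`.
#' @param feature For `"single"`: the feature column to use.
#' @param p_enter,p_remove Thresholds for `"stepwise"`.
#' @return List: `predictions`, `r`, `p`, `F` (squared t of the
#'   prediction/outcome regression), `R2`, `MSE`.
#' @export
loso_evaluate <- function(X, y, model_kind = c("multiple", "stepwise",
                                               "single"),
                          feature = NULL, p_enter = 0.05, p_remove = 0.10) {
  model_kind <- match.arg(model_kind)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects")
  if (stats::sd(y) == 0) stop("outcome has zero variance")
  if (model_kind == "single") {
    if (is.null(feature)) stop("feature required for single predictor")
    X <- X[, feature, drop = FALSE]
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    z <- zscore(X, fit_rows = train)
    Xz <- z$scaled
    fit <- switch(model_kind,
      single = fit_single(Xz[train, 1], y[train]),
      multiple = fit_multiple(Xz[train, , drop = FALSE], y[train]),
      stepwise = fit_stepwise(Xz[train, , drop = FALSE], y[train],
                              p_enter = p_enter, p_remove = p_remove))
    fit$model$z_params <- z[c("center", "scale")]
    preds[i] <- predict(fit$model, Xz[i, , drop = FALSE])
  }
  r <- stats::cor(preds, y)
  if (is.na(r)) {
    ## constant predictions (e.g. stepwise selected nothing in all folds)
    return(list(predictions = preds, r = NA_real_, p = NA_real_,
                F = NA_real_, R2 = NA_real_,
                MSE = mean((100 * (y - preds))^2)))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  list(predictions = preds, r = r, p = p, F = tval^2, R2 = r^2,
       MSE = mean((100 * (y - preds))^2))
}

#' Predictor comparison table
#'
#' Builds the seven-predictor comparison: one row per single-feature
#' predictor (T1%, P300 amplitude, P300 latency, trial variation in
#' amplitude and in latency) plus the multi-feature regular and stepwise
#' models. Each row reports the leave-one-subject-out prediction quality
#' (r between predicted and actual AUC, its p-value, F = t-squared,
#' R2 = r-squared, and MSE on the x100 AUC scale) together with the
#' in-sample correlation of the raw feature (single predictors) or of
#' the fitted values (multi-feature models).
#'
#' @param features Tibble/data frame with the five feature columns
#'   (`t1_percent`, `p300_amplitude`, `p300_latency`, `amp_trial_sd`,
#'   `lat_trial_sd`).
#' @param auc Outcome per subject.
#' @param p_enter,p_remove Stepwise thresholds.
#' @return Tibble with columns `predictor`, `r`, `p`, `F`, `R2`, `MSE`
#'   (all LOSO-based) and `r_insample`.
#' @export
predictor_report <- function(features, auc, p_enter = 0.05,
                             p_remove = 0.10) {
  X <- as.matrix(features[, FEATURE_COLS])
  na_eval <- list(r = NA_real_, p = NA_real_, F = NA_real_, R2 = NA_real_,
                  MSE = NA_real_)
  safe_loso <- function(...) {
    tryCatch(loso_evaluate(...), error = function(e) na_eval)
  }
  rows <- list()
  for (f in FEATURE_COLS) {
    ev <- safe_loso(X, auc, "single", feature = f)
    rows[[f]] <- tibble::tibble(
      predictor = f, r = ev$r, p = ev$p, F = ev$F, R2 = ev$R2,
      MSE = ev$MSE,
      r_insample = suppressWarnings(stats::cor(X[, f], auc)))
  }
  ev <- safe_loso(X, auc, "multiple")
  rows$multiple <- tibble::tibble(
    predictor = "multi_regular", r = ev$r, p = ev$p, F = ev$F, R2 = ev$R2,
    MSE = ev$MSE,
    r_insample = tryCatch(fit_multiple(zscore(X)$scaled, auc)$stats$r,
                          error = function(e) NA_real_))
  ev <- safe_loso(X, auc, "stepwise", p_enter = p_enter,
                  p_remove = p_remove)
  rows$stepwise <- tibble::tibble(
    predictor = "multi_stepwise", r = ev$r, p = ev$p, F = ev$F, R2 = ev$R2,
    MSE = ev$MSE,
    r_insample = tryCatch(
      fit_stepwise(zscore(X)$scaled, auc, p_enter = p_enter,
                   p_remove = p_remove)$stats$r,
      error = function(e) NA_real_))
  do.call(rbind, rows)
}
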