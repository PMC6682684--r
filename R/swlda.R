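## Single-trial target/non-target classification with stepwise linear
## discriminant analysis (SWLDA): temporal decimation, forward/backward
## p-value feature selection on least-squares regression of +/-1 labels,
## and cross-validated AUC.

#' Decimate an epoch by block averaging
#'
#' Averages non-overlapping blocks of `block` consecutive samples per
#' channel; a trailing remainder shorter than `block` is discarded
#' (409 samples with block 24 yield 17 points).
#'
#' @param epoch Channels x samples matrix (a vector is treated as one
#'   channel).
#' @param block Block length in samples.
#' @return Channels x blocks matrix of block means.
#' @export
decimate_epoch <- function(epoch, block = 24) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  n_samp <- ncol(epoch)
  if (n_samp < block) stop("fewer samples than one block")
  n_blk <- n_samp %/% block
  use <- epoch[, seq_len(n_blk * block), drop = FALSE]
  dim(use) <- c(nrow(epoch), block, n_blk)
  out <- apply(use, c(1, 3), mean)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(epoch))
  out
}

#' Build the SWLDA design matrix from an epoch set
#'
#' Decimates every retained epoch and flattens it into one row; feature
#' `(c - 1) * n_blocks + b` is block `b` of channel `c` (channel-major
#' ordering). At 32 channels and 17 blocks this is the 544-dimensional
#' feature vector.
#'
#' @param epochs An `epoch_set` (flagged epochs are excluded).
#' @param block Decimation block length in samples.
#' @return List with `X` (rows x features), `y` (1 = target,
#'   0 = non-target), `n_channels`, `n_blocks`.
#' @export
build_design <- function(epochs, block = 24) {
  ep <- retained_epochs(epochs)
  d <- dim(ep$data)
  n_ep <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  n_blk <- n_samp %/% block
  use <- ep$data[, , seq_len(n_blk * block), drop = FALSE]
  dim(use) <- c(n_ep, n_ch, block, n_blk)
  dec <- apply(use, c(1, 2, 4), mean)          # epochs x ch x blocks
  X <- matrix(aperm(dec, c(1, 3, 2)), nrow = n_ep)  # block fastest within ch
  ## reorder to channel-major: columns currently (blk within ch) ordered by
  ## ch slow — aperm above gives (epoch, blk, ch) flattened blk-fastest,
  ## i.e. feature index = (ch - 1) * n_blk + blk, as documented.
  list(X = X, y = as.integer(ep$labels == "target"),
       n_channels = n_ch, n_blocks = n_blk)
}

## ---- stepwise least-squares core on Gram matrices ----
##
## Forward step: among excluded features, add the one with the smallest
## partial-F p-value if below p_enter. Backward step: remove any included
## feature whose p-value exceeds p_remove. Operates on the centered Gram
## matrix G = Xc'Xc, g = Xc'yc, yy = yc'yc; forward candidate statistics
## are maintained incrementally through a Gram-Schmidt factor W with
## W'W = G[,S] G[S,S]^-1 G[S,].
.stepwise_select <- function(G, g, yy, n, p_enter, p_remove, max_features,
                             tol = 1e-10) {
  p <- length(g)
  d0 <- diag(G)
  eligible <- d0 > tol * max(d0, 1)
  S <- integer(0)
  c_vec <- g
  d_vec <- d0
  RSS <- yy
  W <- matrix(0, 0, p)

  rebuild <- function(S) {
    if (length(S) == 0) {
      list(W = matrix(0, 0, p), c_vec = g, d_vec = d0, RSS = yy)
    } else {
      Gss <- G[S, S, drop = FALSE]
      L <- chol(Gss)                       # upper: t(L) %*% L = Gss
      Wn <- backsolve(L, G[S, , drop = FALSE], transpose = TRUE)
      beta <- backsolve(L, backsolve(L, g[S], transpose = TRUE))
      list(W = Wn,
           c_vec = g - drop(G[, S, drop = FALSE] %*% beta),
           d_vec = pmax(d0 - colSums(Wn^2), 0),
           RSS = max(yy - sum(beta * g[S]), 0))
    }
  }

  iter <- 0L
  max_iter <- 10L * min(max_features, p) + 100L   # cycling guard
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    changed <- FALSE
    ## forward
    if (length(S) < max_features) {
      cand <- which(eligible & !(seq_len(p) %in% S) &
                      d_vec > tol * pmax(d0, 1))
      df2 <- n - length(S) - 2
      if (length(cand) > 0 && df2 > 0) {
        drop_rss <- c_vec[cand]^2 / d_vec[cand]
        denom <- pmax(RSS - drop_rss, 0) / df2
        Fval <- ifelse(denom > 0, drop_rss / denom, Inf)
        pval <- stats::pf(Fval, 1, df2, lower.tail = FALSE)
        j <- cand[which.min(pval)]
        if (min(pval) < p_enter) {
          ## update incremental state
          s_vec <- G[, j]
          if (nrow(W) > 0) s_vec <- s_vec - drop(crossprod(W, W[, j]))
          w_new <- s_vec / sqrt(d_vec[j])
          RSS <- max(RSS - c_vec[j]^2 / d_vec[j], 0)
          c_vec <- c_vec - w_new * (c_vec[j] / sqrt(d_vec[j]))
          d_vec <- pmax(d_vec - w_new^2, 0)
          W <- rbind(W, w_new)
          S <- c(S, j)
          changed <- TRUE
        }
      }
    }
    ## backward
    if (length(S) >= 1) {
      Gss <- G[S, S, drop = FALSE]
      Gi <- tryCatch(chol2inv(chol(Gss)), error = function(e) NULL)
      if (!is.null(Gi)) {
        beta <- drop(Gi %*% g[S])
        RSS_S <- max(yy - sum(beta * g[S]), 0)
        dfres <- n - length(S) - 1
        if (dfres > 0) {
          sigma2 <- RSS_S / dfres
          tsq <- if (sigma2 > 0) beta^2 / (sigma2 * diag(Gi)) else
            rep(Inf, length(S))
          pvals <- stats::pf(tsq, 1, dfres, lower.tail = FALSE)
          worst <- which.max(pvals)
          if (pvals[worst] > p_remove) {
            S <- S[-worst]
            st <- rebuild(S)
            W <- st$W; c_vec <- st$c_vec; d_vec <- st$d_vec; RSS <- st$RSS
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  S
}

#' Fit an SWLDA model
#'
#' Regresses +/-1-coded labels on the features with forward/backward
#' stepwise selection: the forward step adds the excluded feature with
#' the smallest partial-F p-value if it is below `p_enter`; the backward
#' step removes any included feature whose p-value exceeds `p_remove`;
#' iteration stops when neither applies or `max_features` is reached.
#' Weights are the ordinary least-squares coefficients on the final set.
#' If no feature qualifies, an empty (intercept-only) model is returned.
#'
#' @param X Design matrix (rows = epochs).
#' @param y Labels: logical, 0/1 or a two-level factor (positive class =
#'   target).
#' @param max_features Cap on the number of selected features.
#' @param p_enter,p_remove Entry/removal p-value thresholds.
#' @return An object of class `swlda_model`: `selected` (ordered feature
#'   indices), `weights`, `intercept`, thresholds.
#' @export
swlda_fit <- function(X, y, max_features = 60, p_enter = 0.10,
                      p_remove = 0.15) {
  X <- as.matrix(X)
  y01 <- .as_binary(y)
  if (length(unique(y01)) < 2) stop("both classes must be present")
  n <- nrow(X)
  if (n <= 2) stop("need more than 2 rows")
  yc_full <- ifelse(y01 == 1, 1, -1)
  mx <- colMeans(X)
  my <- mean(yc_full)
  Xc <- sweep(X, 2, mx)
  yc <- yc_full - my
  G <- crossprod(Xc)
  g <- drop(crossprod(Xc, yc))
  yy <- sum(yc^2)
  if (all(diag(G) <= 1e-12 * max(1, max(abs(G))))) {
    stop("zero-variance design")
  }
  S <- .stepwise_select(G, g, yy, n, p_enter, p_remove, max_features)
  if (length(S) == 0) {
    model <- list(selected = integer(0), weights = numeric(0),
                  intercept = my, p_enter = p_enter, p_remove = p_remove,
                  max_features = max_features)
  } else {
    beta <- drop(solve(G[S, S, drop = FALSE], g[S]))
    model <- list(selected = S, weights = beta,
                  intercept = my - sum(beta * mx[S]),
                  p_enter = p_enter, p_remove = p_remove,
                  max_features = max_features)
  }
  class(model) <- "swlda_model"
  model
}

.as_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) return(as.integer(y == levels(y)[2]))
  if (is.character(y)) return(as.integer(y == "target"))
  as.integer(y != 0)
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf("SWLDA model: %d selected feature(s), p_enter = %g, p_remove = %g\n",
              length(x$selected), x$p_enter, x$p_remove))
  invisible(x)
}

#' Score rows with an SWLDA model
#'
#' Linear read-out: intercept plus the weighted sum of the selected
#' features. An empty model yields identical scores for all rows.
#'
#' @param model An `swlda_model`.
#' @param X Feature matrix with the same column space the model was fit
#'   on.
#' @return Numeric score per row.
#' @export
swlda_score <- function(model, X) {
  stopifnot(inherits(model, "swlda_model"))
  X <- as.matrix(X)
  if (length(model$selected) == 0) {
    return(rep(model$intercept, nrow(X)))
  }
  if (max(model$selected) > ncol(X)) stop("dimension mismatch")
  drop(X[, model$selected, drop = FALSE] %*% model$weights) + model$intercept
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random target
#' outscores a random non-target, ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (positive class = target, see
#'   [swlda_fit()]).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated single-trial classification AUC
#'
#' Decimates and flattens the retained epochs, shuffles them with `seed`
#' into `k` stratified folds, fits SWLDA on each training split and
#' scores the held-out fold; the subject's performance is the mean of the
#' `k` fold AUCs. A fold whose model is empty contributes AUC 0.5.
#'
#' @param epochs A preprocessed speller `epoch_set`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @param block Decimation block length.
#' @param max_features,p_enter,p_remove SWLDA settings.
#' @return Mean AUC, with per-fold AUCs in attribute `fold_auc`.
#' @export
crossval_auc <- function(epochs, k = 10, seed = 1, block = 24,
                         max_features = 60, p_enter = 0.10,
                         p_remove = 0.15) {
  des <- build_design(epochs, block = block)
  crossval_auc_design(des$X, des$y, k = k, seed = seed,
                      max_features = max_features,
                      p_enter = p_enter, p_remove = p_remove)
}

#' Cross-validated AUC on a prepared design matrix
#'
#' Work-horse behind [crossval_auc()]; exposed for label-permutation
#' null calibration and custom designs.
#'
#' @param X Design matrix.
#' @param y Labels.
#' @param k,seed,max_features,p_enter,p_remove See [crossval_auc()].
#' @return Mean AUC with attribute `fold_auc`.
#' @export
crossval_auc_design <- function(X, y, k = 10, seed = 1,
                                max_features = 60, p_enter = 0.10,
                                p_remove = 0.15) {
  X <- as.matrix(X)
  y01 <- .as_binary(y)
  n <- nrow(X)
  set.seed(as.integer(seed))
  folds <- integer(n)
  for (cls in c(1L, 0L)) {
    idx <- sample(which(y01 == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tapply(y01, folds, function(v) length(unique(v))) < 2)) {
    stop("a fold lacks one of the classes; use fewer folds or more epochs")
  }
  ## pooled sufficient statistics; per-fold training Gram by subtraction
  ypm <- ifelse(y01 == 1, 1, -1)
  Gu <- crossprod(X)
  su <- colSums(X)
  gu <- drop(crossprod(X, ypm))
  sy <- sum(ypm)
  yyu <- sum(ypm^2)

  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    Xte <- X[te, , drop = FALSE]
    yte <- ypm[te]
    nt <- n - sum(te)
    s_t <- su - colSums(Xte)
    sy_t <- sy - sum(yte)
    G <- (Gu - crossprod(Xte)) - tcrossprod(s_t) / nt
    g <- (gu - drop(crossprod(Xte, yte))) - s_t * sy_t / nt
    yy <- (yyu - sum(yte^2)) - sy_t^2 / nt
    S <- .stepwise_select(G, g, yy, nt, p_enter, p_remove, max_features)
    if (length(S) == 0) {
      fold_auc[f] <- 0.5
    } else {
      beta <- drop(solve(G[S, S, drop = FALSE], g[S]))
      scores <- drop(Xte[, S, drop = FALSE] %*% beta)
      fold_auc[f] <- auc(scores, y01[te])
    }
  }
  out <- mean(fold_auc)
  attr(out, "fold_auc") <- fold_auc
  out
}
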