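#' Assemble a sample-by-variable data matrix from averaged spectra
#'
#' Rows are ordered as the spectra are supplied (the cohort simulators emit
#' donor-major, structure-minor order, which fixes the venetian-blind fold
#' composition downstream).
#'
#' @param avg_spectra List of structure-averaged [spectrum()]s sharing one
#'   axis.
#' @return List: `X` (samples x channels), `y` (ages), `sample_id`
#'   ("donor|structure"), `wavenumber`, `structure`.
#' @export
assemble_data_matrix <- function(avg_spectra) {
  stopifnot(length(avg_spectra) >= 1)
  wn <- avg_spectra[[1]]$wavenumber
  X <- t(vapply(avg_spectra, function(s) {
    if (length(s$wavenumber) != length(wn) || any(s$wavenumber != wn)) {
      stop("averaged spectra live on different axes")
    }
    s$intensity
  }, numeric(length(wn))))
  list(X = X,
       y = vapply(avg_spectra, function(s) s$age, numeric(1)),
       sample_id = vapply(avg_spectra, function(s)
         paste(s$donor_id, s$structure, sep = "|"), character(1)),
       wavenumber = wn,
       structure = vapply(avg_spectra, function(s) s$structure, character(1)))
}

#' Mean-center a data matrix and response
#'
#' @param X Samples x variables matrix (>= 2 rows).
#' @param y Optional response vector.
#' @return List `X`, `y`, `x_means`, `y_mean`; centering twice is a no-op and
#'   adding the means back restores the input.
#' @export
mean_center <- function(X, y = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  xm <- colMeans(X)
  out <- list(X = sweep(X, 2, xm), x_means = xm)
  if (!is.null(y)) {
    out$y_mean <- mean(y)
    out$y <- y - out$y_mean
  }
  out
}

#' Principal component analysis of a spectral matrix
#'
#' Mean-centered (unscaled) PCA via the singular value decomposition, the
#' standard treatment for preprocessed spectra.
#'
#' @param X Samples x variables matrix.
#' @param n_pc Number of components to retain.
#' @return List of class `"pca_model"`: `means`, `loadings`
#'   (variables x n_pc, orthonormal), `scores` (samples x n_pc),
#'   `explained` (variance fractions of the retained PCs, non-increasing),
#'   `explained_all`.
#' @export
fit_pca <- function(X, n_pc = 2) {
  X <- as.matrix(X)
  if (n_pc > min(nrow(X) - 1, ncol(X))) {
    stop("n_pc exceeds min(samples - 1, variables)")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(means = pr$center,
         loadings = pr$rotation[, seq_len(n_pc), drop = FALSE],
         scores = pr$x[, seq_len(n_pc), drop = FALSE],
         explained = ev[seq_len(n_pc)],
         explained_all = ev),
    class = "pca_model")
}

#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min selection on Euclidean distances: the first two
#' calibration samples are the globally farthest pair; each further pick
#' maximises the minimum distance to the already-selected set (ties broken
#' by the lower row index).
#'
#' @param X Samples x variables matrix.
#' @param calibration_fraction Fraction of samples for calibration
#'   (in (0, 1); 0.7 gives 84/36 on 120 samples).
#' @return List `calibration`, `prediction`: sorted row indices.
#' @export
kennard_stone_split <- function(X, calibration_fraction = 0.7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (calibration_fraction <= 0 || calibration_fraction >= 1) {
    stop("calibration_fraction must be in (0, 1)")
  }
  n_cal <- round(calibration_fraction * n)
  n_cal <- max(2L, min(n - 1L, n_cal))
  d <- unname(as.matrix(stats::dist(X)))
  far <- arrayInd(which.max(d), dim(d))     # column-major: first max wins
  sel <- sort(c(far[1, 1], far[1, 2]))
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_cal) {
    min_d[sel] <- -Inf
    nxt <- as.integer(which.max(min_d))      # ties -> lowest index
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  list(calibration = as.integer(sort(sel)),
       prediction = as.integer(setdiff(seq_len(n), sel)))
}

#' Fit a PLS regression model (NIPALS)
#'
#' Univariate-response NIPALS with X-only deflation: for each latent
#' variable, the weight vector is the covariance direction
#' `w = X'y / ||X'y||`, the score `t = Xw`, the X-loading `p = X't / t't`
#' and the y-loading `q = y't / t't`, after which X is deflated by `t p'`.
#' Scores of successive latent variables are mutually orthogonal, and with
#' as many latent variables as the rank of X the model reproduces the
#' ordinary least-squares fit.
#'
#' @param X Samples x variables matrix.
#' @param y Response vector (chronological age, years).
#' @param n_lv Number of latent variables
#'   (`1 <= n_lv <= min(samples - 1, variables)`).
#' @return List of class `"pls_model"`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, regression coefficients `coef` and intercept (in
#'   original units), column means, `n_lv`.
#' @export
pls_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop("n_lv must lie in [1, min(samples - 1, variables)]")
  }
  cen <- mean_center(X, y)
  Xc <- cen$X; yc <- cen$y
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { n_lv <- a - 1L; break }   # X fully deflated
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    Xc <- Xc - tcrossprod(t_a, p_a)
  }
  if (n_lv == 0) stop("no usable latent variable (X is constant)")
  W <- W[, seq_len(n_lv), drop = FALSE]
  P <- P[, seq_len(n_lv), drop = FALSE]
  Tm <- Tm[, seq_len(n_lv), drop = FALSE]
  q <- q[seq_len(n_lv)]
  B <- W %*% solve(crossprod(P, W), q)
  structure(
    list(W = W, P = P, T = Tm, q = q, n_lv = n_lv,
         coef = drop(B), intercept = cen$y_mean - sum(cen$x_means * B),
         x_means = cen$x_means, y_mean = cen$y_mean),
    class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param model A [pls_fit()] model.
#' @param X_new New samples x variables matrix (same variables).
#' @param n_lv Number of latent variables to use (default: all fitted).
#' @return Predicted response vector in original units.
#' @export
pls_predict <- function(model, X_new, n_lv = model$n_lv) {
  X_new <- as.matrix(X_new)
  stopifnot(inherits(model, "pls_model"), n_lv >= 1, n_lv <= model$n_lv)
  if (n_lv == model$n_lv) {
    coefs <- model$coef
  } else {
    idx <- seq_len(n_lv)
    W <- model$W[, idx, drop = FALSE]
    P <- model$P[, idx, drop = FALSE]
    coefs <- drop(W %*% solve(crossprod(P, W), model$q[idx]))
  }
  drop(sweep(X_new, 2, model$x_means) %*% coefs) + model$y_mean
}

#' Root mean square error and determination coefficient
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`;
#' `R^2 = 1 - SS_res / SS_tot` (which can be negative for a model worse than
#' the mean).
#'
#' @param y Observed values (non-constant, n >= 2).
#' @param y_hat Predictions, same length.
#' @return List `rmse`, `r2`.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  if (stats::sd(y) == 0) stop("R^2 undefined for a constant response")
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(rmse = sqrt(mean((y - y_hat)^2)), r2 = 1 - ss_res / ss_tot)
}

# Venetian-blind fold labels: sample i (in given row order) goes to fold
# ((i - 1) mod n_folds) + 1.
venetian_folds <- function(n, n_folds) ((seq_len(n) - 1L) %% n_folds) + 1L

#' Venetian-blind cross-validation of a PLS model
#'
#' Splits the samples into `n_folds` interleaved folds by row order (every
#' k-th sample shares a fold), fits NIPALS PLS on each training complement
#' and accumulates held-out predictions for 1 to `max_lv` latent variables.
#' The number of latent variables is chosen as the first local minimum of
#' RMSECV lying within one standard error (over folds) of the global
#' minimum; the global minimum is the fallback.
#'
#' @param X,y Data matrix and response.
#' @param max_lv Largest number of latent variables to scan.
#' @param n_folds Number of folds (default 20, `<= n`).
#' @return List of class `"cv_report"`: `folds`, per-LV `rmsecv` and `r2cv`,
#'   `chosen_lv`, `fold_rmse` (folds x LV), `cv_predictions`
#'   (n x max_lv).
#' @export
venetian_blinds_cv <- function(X, y, max_lv, n_folds = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds > n) stop("more folds than samples")
  if (n_folds < 2) stop("need at least 2 folds")
  folds <- venetian_folds(n, n_folds)
  min_train <- n - max(table(folds))
  cap <- min(min_train - 1, ncol(X))
  if (max_lv > cap) {
    stop("max_lv exceeds the per-fold training capacity (", cap, ")")
  }
  pred <- matrix(NA_real_, n, max_lv)
  fold_rmse <- matrix(NA_real_, n_folds, max_lv)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    fit <- pls_fit(X[!te, , drop = FALSE], y[!te], max_lv)
    for (a in seq_len(fit$n_lv)) {
      pred[te, a] <- pls_predict(fit, X[te, , drop = FALSE], a)
    }
    if (fit$n_lv < max_lv) {         # rank-deficient fold: carry last LV
      for (a in seq(fit$n_lv + 1, max_lv)) pred[te, a] <- pred[te, fit$n_lv]
    }
    fold_rmse[f, ] <- sqrt(colMeans((pred[te, , drop = FALSE] - y[te])^2))
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums((pred - y)^2) / ss_tot
  gm <- which.min(rmsecv)
  se <- stats::sd(fold_rmse[, gm]) / sqrt(n_folds)
  is_local_min <- vapply(seq_len(max_lv), function(a) {
    left_ok <- a == 1 || rmsecv[a] <= rmsecv[a - 1]
    right_ok <- a == max_lv || rmsecv[a] <= rmsecv[a + 1]
    left_ok && right_ok
  }, logical(1))
  cand <- which(is_local_min & rmsecv <= rmsecv[gm] + se)
  chosen <- if (length(cand) > 0) cand[1] else gm
  structure(
    list(folds = folds, rmsecv = rmsecv, r2cv = r2cv,
         chosen_lv = chosen, fold_rmse = fold_rmse, cv_predictions = pred,
         n_folds = n_folds),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold venetian blinds: chosen %d LV, RMSECV %.4g, R2CV %.3f\n",
    x$n_folds, x$chosen_lv, x$rmsecv[x$chosen_lv], x$r2cv[x$chosen_lv]))
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with normalised
#' weight vectors and `SSY_a = q_a^2 t_a't_a` the response variance captured
#' by latent variable `a`; the squared scores average to 1 over variables.
#'
#' @param model A [pls_fit()] model.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  ssy <- model$q^2 * colSums(model$T^2)
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  drop(sqrt(p * (w2 %*% ssy) / sum(ssy)))
}
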