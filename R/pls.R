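#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a univariate-response PLS regression by the NIPALS algorithm on
#' centred (and, by default, unit-variance-scaled) predictors and centred
#' response, deflating the predictor matrix after each component. PLS
#' projects the collinear spectral predictors onto a small number of
#' latent components maximizing covariance with the response, which is why
#' it suits diversity-from-spectra models where wavelengths are far more
#' numerous than plots.
#'
#' @param X Numeric predictor matrix (plots x wavelengths).
#' @param y Numeric response vector.
#' @param ncomp Number of latent components, at most `min(nrow(X) - 1,
#'   ncol(X))`.
#' @param scale Scale predictor columns to unit variance (default `TRUE`);
#'   constant columns get scale 1 with a warning.
#' @return Object of class `"pls_model"`: centring/scaling constants,
#'   weight (`W`), loading (`P`), score (`scores`) matrices, response
#'   loadings `q`, and `coefficients(model, ncomp)` gives original-unit
#'   regression coefficients (first element = intercept).
#' @export
pls_fit <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response: nothing to fit", call. = FALSE)
  max_comp <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > max_comp) {
    stop("ncomp must be in 1..", max_comp, call. = FALSE)
  }

  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (scale && any(x_scale == 0)) {
    warning("constant predictor column(s); left unscaled", call. = FALSE)
    x_scale[x_scale == 0] <- 1
  }
  y_center <- mean(y)

  Xr <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yr <- y - y_center

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xr, yr))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # residual X carries no covariance with y
    w <- w / wn
    t_a <- drop(Xr %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(Xr, t_a)) / tt
    q_a <- sum(yr * t_a) / tt
    Xr <- Xr - tcrossprod(t_a, p_a)
    yr <- yr - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; TT[, a] <- t_a; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) stop("no usable PLS component (X orthogonal to y)", call. = FALSE)
  if (a_used < ncomp) {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    TT <- TT[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
  }

  structure(list(ncomp = a_used, x_center = x_center, x_scale = x_scale,
                 y_center = y_center, W = W, P = P, scores = TT, q = q,
                 scaled = scale),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictors%s\n",
              x$ncomp, length(x$x_center),
              if (x$scaled) " (scaled)" else ""))
  invisible(x)
}

#' Regression coefficients of a PLS model
#'
#' @param object A `pls_model`.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector: intercept followed by one coefficient per
#'   predictor, in original predictor units.
#' @export
coef.pls_model <- function(object, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 0L, ncomp <= object$ncomp)
  if (ncomp == 0L) {
    return(c(intercept = object$y_center,
             stats::setNames(numeric(length(object$x_center)),
                             names(object$x_center))))
  }
  W <- object$W[, seq_len(ncomp), drop = FALSE]
  P <- object$P[, seq_len(ncomp), drop = FALSE]
  q <- object$q[seq_len(ncomp)]
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b <- b_scaled / object$x_scale
  c(intercept = object$y_center - sum(object$x_center * b),
    stats::setNames(b, names(object$x_center)))
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with the same predictor columns as the
#'   training data.
#' @param ncomp Number of components (0 gives the training-response mean).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  b <- coef.pls_model(object, ncomp = ncomp)
  drop(b[1] + newdata %*% b[-1])
}

#' Choose the number of PLS components by k-fold cross-validation
#'
#' Random fold assignment (seeded), candidate counts `1..max_components`,
#' PRESS (sum of squared held-out prediction errors) per candidate.
#' Selection rule: `"one_se"` (default) picks the smallest count whose
#' PRESS is within one standard error (over folds) of the minimum — the
#' usual parsimony rule for cross-validated model size, which stabilizes
#' selection when the PRESS curve is flat beyond the true dimension;
#' `"min"` picks the PRESS minimum, ties to the smaller count.
#' `k_folds = n` gives leave-one-out (with `rule = "min"` recommended,
#' as one-sample folds make the SE estimate noisy).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param k_folds Number of folds (default 10).
#' @param max_components Largest candidate count; capped by fold training
#'   sizes.
#' @param seed Integer seed for the fold assignment.
#' @param scale Passed to [pls_fit()].
#' @param rule Selection rule, `"one_se"` or `"min"`.
#' @return List: `n_components` (selected), `cv_table` (data frame
#'   `ncomp`, `press`, `rmsep`, `se`), `folds` (assignment vector).
#' @export
cv_select_components <- function(X, y, k_folds = 10, max_components = 10,
                                 seed = 1, scale = TRUE,
                                 rule = c("one_se", "min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_folds < 2 || k_folds > n) {
    stop("config error: k_folds must be in 2..n", call. = FALSE)
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), n))
  min_train <- n - max(table(folds))
  max_components <- min(max_components, min_train - 1L, ncol(X))
  if (max_components < 1L) stop("config error: folds too small", call. = FALSE)

  fold_mse <- matrix(0, k_folds, max_components)  # per-fold mean sq. error
  for (k in seq_len(k_folds)) {
    test <- folds == k
    fit <- pls_fit(X[!test, , drop = FALSE], y[!test],
                   ncomp = max_components, scale = scale)
    for (a in seq_len(max_components)) {
      a_eff <- min(a, fit$ncomp)
      pred <- predict.pls_model(fit, X[test, , drop = FALSE], ncomp = a_eff)
      fold_mse[k, a] <- mean((y[test] - pred)^2)
    }
  }
  press <- colSums(fold_mse * as.numeric(table(folds)))
  se <- apply(fold_mse, 2, stats::sd) / sqrt(k_folds)
  cv_table <- data.frame(ncomp = seq_len(max_components), press = press,
                         rmsep = sqrt(press / n), se = se)
  best <- which.min(press)
  n_components <- if (rule == "min") best else {
    cv_mean <- press / n
    min(which(cv_mean <= cv_mean[best] + se[best]))
  }
  list(n_components = cv_table$ncomp[n_components], cv_table = cv_table,
       folds = folds)
}

#' Train/test evaluation of a diversity-from-spectra PLS model
#'
#' The full workflow for one diversity index and trophic level: a seeded
#' 70/30 train/test split, component count chosen by 10-fold
#' cross-validation on the training set, final model fit on the training
#' set, and accuracy (R-squared, RMSE, bias) measured on the held-out
#' test set.
#'
#' @param X Plot-spectra matrix (plots x wavelengths).
#' @param y Diversity values (one per plot).
#' @param train_fraction Fraction of plots used for training (default 0.7).
#' @param k_folds,max_components,scale Passed to [cv_select_components()].
#' @param seed Integer seed driving both the split and the CV folds.
#' @return List: `metrics` ([fit_metrics()] row on the test set),
#'   `predictions` (data frame `observed`, `predicted` for test plots),
#'   `n_components`, `cv_table`, `model`, `train_index`.
#' @export
evaluate_diversity_model <- function(X, y, train_fraction = 0.7, k_folds = 10,
                                     max_components = 10, seed = 1,
                                     scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 samples for a 70/30 evaluation", call. = FALSE)
  set.seed(seed)
  train <- sort(sample.int(n, round(train_fraction * n)))
  test <- setdiff(seq_len(n), train)

  sel <- cv_select_components(X[train, , drop = FALSE], y[train],
                              k_folds = min(k_folds, length(train)),
                              max_components = max_components,
                              seed = seed + 1L, scale = scale)
  model <- pls_fit(X[train, , drop = FALSE], y[train],
                   ncomp = sel$n_components, scale = scale)
  pred <- predict.pls_model(model, X[test, , drop = FALSE])
  list(metrics = fit_metrics(y[test], pred),
       predictions = data.frame(observed = y[test], predicted = pred),
       n_components = model$ncomp, cv_table = sel$cv_table, model = model,
       train_index = train)
}
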