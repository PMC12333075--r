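# Independent oracles and small fixture builders shared across tests.

# Exhaustive active-set enumeration for small NNLS problems: solve the
# unconstrained least squares on every support, keep feasible solutions,
# return the best. Independent of the package's active-set implementation.
nnls_enumerate <- function(E, y) {
  n <- ncol(E)
  best <- list(objective = sum(y^2), coef = numeric(n))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    b <- tryCatch(qr.solve(E[, S, drop = FALSE], y), error = function(e) NULL)
    if (is.null(b) || any(b < -1e-12)) next
    r <- y - E[, S, drop = FALSE] %*% b
    obj <- sum(r^2)
    if (obj < best$objective) {
      coef <- numeric(n)
      coef[S] <- b
      best <- list(objective = obj, coef = coef)
    }
  }
  best
}

# SIMPLS for a univariate response: an algorithm independent of the
# package's NIPALS implementation, used as a cross-algorithm oracle.
simpls_predictor <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  xs[xs == 0] <- 1
  X0 <- sweep(sweep(X, 2, xm), 2, xs, "/")
  y0 <- y - mean(y)
  s <- crossprod(X0, y0)
  R <- matrix(0, ncol(X), ncomp)
  V <- matrix(0, ncol(X), ncomp)
  for (a in seq_len(ncomp)) {
    r <- s
    t_a <- drop(X0 %*% r)
    nt <- sqrt(sum(t_a^2))
    r <- r / nt
    t_a <- t_a / nt
    p <- crossprod(X0, t_a)
    v <- p
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
  }
  TT <- X0 %*% R
  b <- drop(R %*% qr.solve(crossprod(TT), crossprod(TT, y0))) / xs
  intercept <- mean(y) - sum(xm * b)
  function(newX) drop(intercept + as.matrix(newX) %*% b)
}

# Minimal valid library on an arbitrary grid.
toy_library <- function(wavelength_nm = 400:409,
                        rf = NULL, n = 2, role = "plot") {
  if (is.null(rf)) {
    rf <- matrix(seq(0.1, 0.5, length.out = length(wavelength_nm) * n),
                 ncol = n)
  }
  ids <- paste0("s", seq_len(ncol(rf)))
  colnames(rf) <- ids
  meta <- data.frame(sample_id = ids, role = role,
                     species = if (role == "endmember") paste0("sp", seq_along(ids)) else NA,
                     plot_id = if (role == "plot") ids else NA,
                     trophic_level = "minerotrophic", quantity = "HCRF")
  spectral_library(wavelength_nm, rf, meta)
}

# Small endmember library + exact-mixture plots for unmixing tests.
exact_mixture_fixture <- function(seed = 1, n_plots = 8, noise_sd = 0) {
  set.seed(seed)
  wl <- 400:449
  E <- cbind(e1 = 0.2 + 0.3 * plogis((wl - 420) / 5),
             e2 = 0.5 - 0.004 * (wl - 400),
             e3 = 0.1 + 0.2 * exp(-0.5 * ((wl - 430) / 8)^2))
  covers <- t(vapply(seq_len(n_plots), function(i) {
    g <- rgamma(3, 1)
    100 * g / sum(g)
  }, numeric(3)))
  Y <- E %*% t(covers / 100) + matrix(rnorm(length(wl) * n_plots, 0, noise_sd),
                                      nrow = length(wl))
  list(wl = wl, E = E, covers = covers, Y = Y)
}
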