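## Univariate and bivariate autoregressive fits and the per-window admission
## diagnostics: KPSS level-stationarity, Durbin-Watson residual whiteness and
## Ding-style model consistency. All fits are ordinary least squares with an
## intercept, and univariate/bivariate models of the same window share the
## same effective samples (p+1 .. N), which is what guarantees the nesting
## inequality behind the nonnegativity of GC.

ols_fit <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular AR design (rank-deficient regressors)")
  beta <- qr.coef(qr_x, Y)
  resid <- Y - X %*% beta
  list(beta = beta, resid = resid)
}

#' Fit a univariate AR(p) model by least squares
#'
#' Regresses `x[t]` on an intercept and `x[t-1] .. x[t-p]`. The residual
#' variance uses divisor `n_effective = N - p` (maximum-likelihood
#' convention); GC is a variance ratio over a shared effective sample, so
#' only consistency of the convention matters, and it is fixed here so that
#' results are exactly reproducible.
#'
#' @param x numeric vector (finite values).
#' @param p lag order.
#' @return an object of class `ar_fit`: `order`, `intercept`, `coef` (lag
#'   1..p), `residuals`, `sigma2`, `n_effective`.
#' @export
fit_ar <- function(x, p) {
  stopifnot(p >= 1, all(is.finite(x)))
  if (length(x) <= 10 * p) stop("series too short for order ", p, " (need > 10p samples)")
  X <- lag_matrix(list(x), p)
  y <- x[(p + 1):length(x)]
  fit <- ols_fit(X, y)
  res <- drop(fit$resid)
  n_eff <- length(y)
  structure(list(order = p, intercept = fit$beta[1], coef = fit$beta[-1],
                 residuals = res, sigma2 = sum(res^2) / n_eff,
                 n_effective = n_eff),
            class = "ar_fit")
}

#' Fit a bivariate VAR(p) model by least squares
#'
#' Two-equation OLS on the shared design (intercept + lags 1..p of both
#' series), over the same effective samples as the univariate fits of either
#' series. The full 2x2 residual covariance is returned; its off-diagonal is
#' the instantaneous-causality quantity (covariance of the bivariate
#' prediction errors).
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param p lag order.
#' @return an object of class `var2_fit`: `order`, `intercept` (length 2),
#'   `A` (2 x 2 x p coefficient array, `A[i, j, k]` = effect of `x_j[t-k]` on
#'   `x_i[t]`), `residuals` (n_eff x 2), `Sigma` (2 x 2), `n_effective`.
#' @export
fit_var2 <- function(x1, x2, p) {
  stopifnot(p >= 1, length(x1) == length(x2),
            all(is.finite(x1)), all(is.finite(x2)))
  n <- length(x1)
  if (n <= 10 * p) stop("series too short for order ", p, " (need > 10p samples)")
  X <- lag_matrix(list(x1, x2), p)
  Y <- cbind(x1[(p + 1):n], x2[(p + 1):n])
  fit <- ols_fit(X, Y)
  res <- fit$resid
  n_eff <- nrow(Y)
  A <- array(0, dim = c(2, 2, p))
  for (k in seq_len(p)) {
    A[1, 1, k] <- fit$beta[1 + k, 1];      A[2, 1, k] <- fit$beta[1 + k, 2]
    A[1, 2, k] <- fit$beta[1 + p + k, 1];  A[2, 2, k] <- fit$beta[1 + p + k, 2]
  }
  structure(list(order = p, intercept = fit$beta[1, ], A = A,
                 residuals = res, Sigma = crossprod(res) / n_eff,
                 n_effective = n_eff),
            class = "var2_fit")
}

#' Select the VAR order by BIC over a sample of windows
#'
#' Sums the bivariate BIC, `n_eff * log det(Sigma) + k * log(n_eff)` with
#' `k = 2(2p + 1)` parameters, across the supplied window pairs and returns
#' the minimizing order in `1..p_max`. The pipeline default bypasses this and
#' uses a fixed order of 6, which in the source study did not degrade model
#' consistency relative to per-patient BIC orders.
#'
#' @param window_pairs list of 2-column matrices (one window pair each).
#' @param p_max largest order considered.
#' @return the selected order (integer).
#' @export
select_order_bic <- function(window_pairs, p_max) {
  stopifnot(p_max >= 1, length(window_pairs) >= 1)
  bic <- numeric(p_max)
  for (p in seq_len(p_max)) {
    tot <- 0
    for (w in window_pairs) {
      f <- fit_var2(w[, 1], w[, 2], p)
      k_par <- 2 * (2 * p + 1)
      tot <- tot + f$n_effective * determinant(f$Sigma, logarithm = TRUE)$modulus +
        k_par * log(f$n_effective)
    }
    bic[p] <- tot
  }
  which.min(bic)
}

## KPSS critical values for level stationarity (Kwiatkowski et al. 1992,
## Table 1, eta_mu row).
kpss_critical <- c("0.1" = 0.347, "0.05" = 0.463, "0.025" = 0.574, "0.01" = 0.739)

#' KPSS test for level stationarity
#'
#' Statistic `sum(S_t^2) / (n^2 * lrv)` where `S_t` are partial sums of the
#' demeaned series and `lrv` is the Bartlett-weighted long-run variance with
#' the short truncation lag `floor(4 (n/100)^(1/4))`. The null hypothesis is
#' stationarity, so windows whose statistic exceeds the critical value are
#' excluded from GC estimation. An exactly constant window is stationary by
#' convention (statistic 0).
#'
#' @param x numeric vector, length >= 64.
#' @param level critical level; one of 0.1, 0.05, 0.025, 0.01 (default 0.01).
#' @param lags truncation lag; defaults to the short rule above.
#' @return list with `statistic`, `stationary` flag, `lags`, `level`.
#' @export
kpss_test <- function(x, level = 0.01, lags = NULL) {
  n <- length(x)
  stopifnot(n >= 64)
  crit <- kpss_critical[as.character(level)]
  if (is.na(crit)) stop("level must be one of ", paste(names(kpss_critical), collapse = ", "))
  e <- x - mean(x)
  if (sum(e^2) < .Machine$double.eps * n) {
    return(list(statistic = 0, stationary = TRUE, lags = 0L, level = level))
  }
  if (is.null(lags)) lags <- floor(4 * (n / 100)^0.25)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      s2 <- s2 + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  S <- cumsum(e)
  stat <- sum(S^2) / (n^2 * s2)
  list(statistic = stat, stationary = stat < crit, lags = as.integer(lags),
       level = level)
}

#' Durbin-Watson statistic on AR residuals
#'
#' `DW = sum(diff(e)^2) / sum(e^2)`, approximately `2(1 - rho)` for lag-1
#' residual autocorrelation `rho`. The residuals pass when the implied
#' `|rho| = |1 - DW/2|` stays inside the approximate 95% whiteness band
#' `2/sqrt(n)`; windows with autocorrelated residuals are excluded.
#'
#' @param residuals numeric vector, length >= 10.
#' @return list with `statistic`, `ok` flag, `rho`.
#' @export
durbin_watson <- function(residuals) {
  n <- length(residuals)
  stopifnot(n >= 10)
  denom <- sum(residuals^2)
  if (denom == 0) stop("all-zero residuals: perfect fit is not a valid AR residual series")
  dw <- sum(diff(residuals)^2) / denom
  rho <- 1 - dw / 2
  list(statistic = dw, ok = abs(rho) <= 2 / sqrt(n), rho = rho)
}

stacked_correlations <- function(x1, x2, p) {
  a1 <- stats::acf(x1, lag.max = p, plot = FALSE, demean = TRUE)$acf[-1]
  a2 <- stats::acf(x2, lag.max = p, plot = FALSE, demean = TRUE)$acf[-1]
  cc <- stats::ccf(x1, x2, lag.max = p, plot = FALSE)$acf[, 1, 1]
  c(a1, a2, cc)
}

#' Ding-style consistency of a fitted bivariate AR model
#'
#' Simulates the fitted VAR once, at the window's own length, with
#' innovations resampled jointly from the fit residuals (preserving their
#' instantaneous covariance), and compares the stacked auto- and
#' cross-correlations up to lag `p` between data and simulation:
#' `100 * (1 - ||R_sim - R_data|| / ||R_data||)`, clipped to `[0, 100]`.
#' Windows under 70% are excluded from GC estimation. An unstable fitted VAR
#' scores 0.
#'
#' @param x1,x2 the window data the fit came from.
#' @param fit a `var2_fit` of `(x1, x2)`.
#' @param seed integer seed for the innovation resampling.
#' @param lag_max correlation lags compared; defaults to the fit order. Fix
#'   it across fits of different orders when comparing their consistency, so
#'   all candidates are scored against the same correlation structure.
#' @return consistency in percent.
#' @export
ar_consistency <- function(x1, x2, fit, seed = 1, lag_max = fit$order) {
  stopifnot(inherits(fit, "var2_fit"), length(x1) == length(x2))
  p <- fit$order
  Aflat <- matrix(0, 2, 2 * p)
  for (k in seq_len(p)) Aflat[, (k - 1) * 2 + (1:2)] <- fit$A[, , k]
  if (spectral_radius(Aflat) >= 1) return(0)
  n <- length(x1)
  burn <- 100L
  sim <- with_seed(seed, {
    idx <- sample.int(nrow(fit$residuals), n + burn, replace = TRUE)
    innov <- t(fit$residuals[idx, , drop = FALSE]) + fit$intercept
    var_sim_cpp(Aflat, innov)
  })
  sim <- sim[, (burn + 1):(burn + n), drop = FALSE]
  r_data <- stacked_correlations(x1, x2, lag_max)
  r_sim <- stacked_correlations(sim[1, ], sim[2, ], lag_max)
  cons <- 100 * (1 - sqrt(sum((r_sim - r_data)^2)) / sqrt(sum(r_data^2)))
  min(100, max(0, cons))
}
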