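# Two-sided censored (Tobit) regression by maximum likelihood. The DEA
# efficiency score lives in (0, 1] with mass at 1, so the latent-normal model
# is censored at both bounds: interior observations contribute the normal
# density, bound observations the corresponding tail probability.

tobit_loglik <- function(theta, y, X, lower, upper) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  s <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  ll <- numeric(length(y))
  at_lo <- y <= lower
  at_hi <- y >= upper
  mid <- !at_lo & !at_hi
  ll[mid] <- dnorm((y[mid] - mu[mid]) / s, log = TRUE) - log(s)
  if (any(at_lo)) ll[at_lo] <- pnorm((lower - mu[at_lo]) / s, log.p = TRUE)
  if (any(at_hi)) ll[at_hi] <- pnorm((upper - mu[at_hi]) / s,
                                     lower.tail = FALSE, log.p = TRUE)
  sum(ll)
}

tobit_score <- function(theta, y, X, lower, upper) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  s <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  at_lo <- y <= lower
  at_hi <- y >= upper
  mid <- !at_lo & !at_hi
  gmu <- numeric(length(y))   # dll/dmu
  gls <- numeric(length(y))   # dll/dlog s
  z <- (y - mu) / s
  gmu[mid] <- z[mid] / s
  gls[mid] <- z[mid]^2 - 1
  if (any(at_lo)) {
    zl <- (lower - mu[at_lo]) / s
    mills <- exp(dnorm(zl, log = TRUE) - pnorm(zl, log.p = TRUE))
    gmu[at_lo] <- -mills / s
    gls[at_lo] <- -mills * zl
  }
  if (any(at_hi)) {
    zu <- (upper - mu[at_hi]) / s
    mills <- exp(dnorm(zu, log = TRUE) -
                   pnorm(zu, lower.tail = FALSE, log.p = TRUE))
    gmu[at_hi] <- mills / s
    gls[at_hi] <- mills * zu
  }
  c(drop(crossprod(X, gmu)), sum(gls))
}

#' Tobit regression with two-sided censoring
#'
#' Maximum-likelihood fit of a latent normal regression observed only inside
#' `[lower, upper]` (default the efficiency-score bounds 0 and 1). Starts
#' from ordinary least squares with the residual standard deviation as the
#' initial scale, optimizes over (beta, log sigma) by BFGS with the analytic
#' score, and reports observed-information standard errors with
#' normal-approximation Wald p-values.
#'
#' @param y response in `[lower, upper]`.
#' @param x covariate data frame or matrix (no intercept column; one is
#'   added).
#' @param lower,upper censoring bounds.
#' @param max_iter BFGS iteration cap.
#' @return An object of class `"tobit_fit"`: coefficients (intercept first),
#'   `sigma`, standard errors, p-values, log-likelihood, censoring counts.
#'   `tidy()` gives the coefficient table (optionally scaled, e.g.
#'   `scale = 1000` for per-mille reporting), `glance()` the fit summary.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- pmin(pmax(0.8 + 0.1 * x + rnorm(500, sd = 0.05), 0), 1)
#' fit <- fit_tobit(y, data.frame(x = x))
#' tidy(fit)
fit_tobit <- function(y, x, lower = 0, upper = 1, max_iter = 500) {
  X <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(x)))
  storage.mode(X) <- "double"
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) abort("`y` and `x` must have the same number of rows")
  if (anyNA(y) || anyNA(X)) abort("missing values are not allowed")
  if (any(y < lower - 1e-12) || any(y > upper + 1e-12)) {
    abort(sprintf("`y` must lie within [%g, %g]", lower, upper))
  }
  if (n <= p + 2) abort("need n > p + 2 observations")
  if (qr(X)$rank < p) abort("`x` is not of full column rank")
  n_lo <- sum(y <= lower)
  n_hi <- sum(y >= upper)
  if (n_lo + n_hi == n) {
    abort("all observations are censored; the Tobit likelihood is degenerate")
  }
  censored <- n_lo > 0 || n_hi > 0
  # standardize covariates for the optimizer (coefficient equivariance makes
  # this exact); raw scales like kcal/d otherwise condition the Hessian badly
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, sd))
  if (any(scl == 0)) abort("`x` contains a constant column")
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  ols <- lm.fit(Xs, y)
  sigma0 <- max(sd(ols$residuals), 1e-4)
  theta0 <- c(ols$coefficients, log(sigma0))
  negll <- function(th) -tobit_loglik(th, y, Xs, lower, upper)
  neggr <- function(th) -tobit_score(th, y, Xs, lower, upper)
  opt <- optim(theta0, negll, neggr, method = "BFGS", hessian = TRUE,
               control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0) {
    abort(sprintf(
      "Tobit fit did not converge (code %d) after %d iterations: %s",
      opt$convergence, max_iter, opt$message %||% "see optim trace"))
  }
  H <- opt$hessian
  Vs <- tryCatch(solve(H), error = function(e) {
    abort("observed information is singular; check covariate scaling/collinearity")
  })
  # map (beta_std, log sigma) back to the raw covariate scale
  J <- diag(p + 1)
  J[1, seq_len(p)] <- -ctr / scl
  J[1, 1] <- 1
  diag(J)[seq_len(p)] <- 1 / scl
  V <- J %*% Vs %*% t(J)
  beta <- drop(J %*% opt$par)[seq_len(p)]
  se <- sqrt(pmax(diag(V), 0))[seq_len(p)]
  zstat <- beta / se
  structure(
    list(coefficients = setNames(unname(beta), colnames(X)),
         sigma = unname(exp(opt$par[p + 1])),
         se = setNames(se, colnames(X)),
         statistic = setNames(zstat, colnames(X)),
         p_value = setNames(2 * pnorm(-abs(zstat)), colnames(X)),
         logLik = -opt$value,
         logLik_start = tobit_loglik(theta0, y, X, lower, upper),
         vcov = V,
         n = n, n_lower = n_lo, n_upper = n_hi,
         n_interior = n - n_lo - n_hi,
         lower = lower, upper = upper,
         censored = censored,
         terms = colnames(X)),
    class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("<tobit_fit> n = %d (%d at lower, %d interior, %d at upper), sigma = %.4g\n",
              x$n, x$n_lower, x$n_interior, x$n_upper, x$sigma))
  print(tidy(x), ...)
  invisible(x)
}

#' @param scale multiply estimates and standard errors for display (the
#'   regression tables report coefficients x 1000).
#' @rdname fit_tobit
#' @export
tidy.tobit_fit <- function(x, scale = 1, ...) {
  tibble(term = x$terms,
         estimate = unname(x$coefficients) * scale,
         std.error = unname(x$se) * scale,
         statistic = unname(x$statistic),
         p.value = unname(x$p_value))
}

#' @export
glance.tobit_fit <- function(x, ...) {
  tibble(n = x$n, n_lower = x$n_lower, n_interior = x$n_interior,
         n_upper = x$n_upper, sigma = x$sigma, logLik = x$logLik,
         df = length(x$coefficients) + 1)
}

#' @export
autoplot.tobit_fit <- function(object, scale = 1000, ...) {
  df <- tidy(object, scale = scale)
  df <- df[df$term != "(Intercept)", ]
  df$lo <- df$estimate - qnorm(0.975) * df$std.error
  df$hi <- df$estimate + qnorm(0.975) * df$std.error
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::labs(x = sprintf("Coefficient x %g (efficiency-score scale)",
                              scale),
                  y = NULL, title = "Tobit regression on efficiency score") +
    ggplot2::theme_minimal()
}

#' Univariate Tobit screen
#'
#' One single-covariate Tobit fit per candidate covariate, assembled into a
#' long coefficient table (intercept rows dropped).
#'
#' @param data data frame with the response and covariates.
#' @param response response column name.
#' @param covariates character vector of covariate columns.
#' @param lower,upper censoring bounds.
#' @param scale display scaling of estimates/SEs.
#' @return A tibble with one row per covariate plus a `fits` attribute
#'   holding the underlying `tobit_fit` objects.
#' @export
univariate_screen <- function(data, response, covariates, lower = 0,
                              upper = 1, scale = 1) {
  stop_if_not_df(data)
  check_cols(data, c(response, covariates))
  fits <- lapply(covariates, function(v) {
    fit_tobit(data[[response]], data[v], lower = lower, upper = upper)
  })
  names(fits) <- covariates
  rows <- purrr::map2(fits, covariates, function(f, v) {
    t <- tidy(f, scale = scale)
    t[t$term != "(Intercept)", ]
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) from the ordinary least-squares regression of
#' covariate k on the remaining covariates. Exact collinearity yields an
#' infinite VIF.
#'
#' @param x data frame or matrix of covariates (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' vif(data.frame(a = c(1, 2, 3, 5), b = c(2, 1, 4, 3)))
vif <- function(x) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (ncol(X) < 2) abort("VIF needs at least 2 covariates")
  if (anyNA(X)) abort("missing values are not allowed")
  vapply(seq_len(ncol(X)), function(k) {
    yk <- X[, k]
    Zk <- cbind(1, X[, -k, drop = FALSE])
    fit <- lm.fit(Zk, yk)
    tss <- sum((yk - mean(yk))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(colnames(X))
}
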