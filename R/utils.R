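# Internal numerical helpers shared across modules.

# Quantile of a normal truncated to [lower, upper].
qtruncnorm_ <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  q <- qnorm(plo + p * (phi - plo), mean, sd)
  # p = 0/1 in double precision would escape the support
  pmin(pmax(q, lower), upper)
}

# Mean and sd of a normal(mu, sigma) truncated to [lower, upper] (closed form).
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  # dnorm(+-Inf) = 0 and a*dnorm(a) -> 0, but guard the products against Inf*0
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the truncated distribution on [lower, upper]
# has the requested mean and sd. When the bounds are > 5 sd away from the
# target the parent parameters are returned unchanged (truncation negligible).
solve_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  near <- min(abs(c(lower, upper) - mean), na.rm = TRUE)
  if (near > 5 * sd) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(theta) {
    mo <- truncnorm_moments(theta[1], exp(theta[2]), lower, upper)
    (mo[["mean"]] - mean)^2 / sd^2 + (mo[["sd"]] - sd)^2 / sd^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  if (fit$value > 1e-4) {
    abort(sprintf(
      "cannot match a truncated normal on [%g, %g] to mean %g, sd %g",
      lower, upper, mean, sd))
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Gauss-Hermite nodes/weights (Golub-Welsch), rescaled for E[f(Z)], Z ~ N(0,1).
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = sqrt(2) * e$values[idx],
       weights = (e$vectors[1, idx])^2)
}

# All compositions of k into n non-negative parts, as an (n_comp x n) matrix.
# Cached per (k, n): reused heavily by the DEA grid oracle.
compositions_env <- new.env(parent = emptyenv())
compositions <- function(k, n) {
  key <- paste0(k, "_", n)
  hit <- compositions_env[[key]]
  if (!is.null(hit)) return(hit)
  k <- as.integer(k)
  n <- as.integer(n)
  out <- if (n == 1L) {
    matrix(k, 1L, 1L)
  } else {
    # stars and bars: n-1 dividers among k+n-1 slots; successive differences
    # of the divider positions give the parts
    bars <- utils::combn(k + n - 1L, n - 1L)
    bounds <- rbind(0L, bars, k + n)
    t(bounds[-1L, , drop = FALSE] - bounds[-nrow(bounds), , drop = FALSE]) - 1L
  }
  compositions_env[[key]] <- out
  out
}

# Cached integer offset grid {-span..span}^d for the oracle refinement pass.
offset_env <- new.env(parent = emptyenv())
offset_grid <- function(d, span) {
  key <- paste0(d, "_", span)
  hit <- offset_env[[key]]
  if (!is.null(hit)) return(hit)
  out <- as.matrix(expand.grid(rep(list(seq.int(-span, span)), d)))
  dimnames(out) <- NULL
  offset_env[[key]] <- out
  out
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_df <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame", arg))
  }
}

check_cols <- function(data, cols, arg = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("column(s) %s not found in `%s`",
                  paste0("'", missing, "'", collapse = ", "), arg))
  }
  invisible(TRUE)
}
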