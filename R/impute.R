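# Chained-equation multiple imputation with predictive mean matching,
# quickpred-style predictor selection, Rubin's-rules pooling and backward
# elimination with a cross-dataset retention rule.

#' Quickpred-style predictor selection
#'
#' For every incomplete target variable, selects as predictors the variables
#' whose absolute pairwise-complete correlation with the target — either
#' with its observed values or with its missingness indicator — is at least
#' `mincor`, and whose proportion of usable cases (observed predictor among
#' the target's missing rows) is at least `minpuc`. Forced variables are
#' always included in every imputation model regardless of correlation.
#'
#' @param data data frame (numeric columns are candidate predictors).
#' @param mincor minimum absolute correlation.
#' @param minpuc minimum proportion of usable cases.
#' @param forced character vector of always-included predictors.
#' @param exclude columns never used as predictors or targets.
#' @return A logical matrix with one row per incomplete target and one
#'   column per candidate predictor (`TRUE` = use). Zero rows when the data
#'   are complete.
#' @export
quickpred <- function(data, mincor = 0.1, minpuc = 0.25, forced = NULL,
                      exclude = NULL) {
  stop_if_not_df(data)
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  num <- setdiff(num, exclude)
  miss <- vapply(data[num], anyNA, TRUE)
  targets <- num[miss]
  for (v in targets) {
    if (all(is.na(data[[v]]))) {
      abort(sprintf("'%s' has no observed values and cannot be imputed", v))
    }
  }
  bad <- setdiff(forced, num)
  if (length(bad)) {
    abort(sprintf("forced predictor(s) not found or non-numeric: %s",
                  paste(bad, collapse = ", ")))
  }
  P <- matrix(FALSE, length(targets), length(num),
              dimnames = list(targets, num))
  for (tv in targets) {
    ty <- data[[tv]]
    rind <- as.numeric(is.na(ty))
    for (pv in setdiff(num, tv)) {
      px <- data[[pv]]
      ok <- stats::complete.cases(ty, px)
      cval <- if (sum(ok) > 2 && sd(ty[ok]) > 0 && sd(px[ok]) > 0) {
        abs(cor(ty[ok], px[ok]))
      } else 0
      okr <- !is.na(px)
      crind <- if (sd(rind) > 0 && sum(okr) > 2 && sd(px[okr]) > 0 &&
                   sd(rind[okr]) > 0) {
        abs(cor(rind[okr], px[okr]))
      } else 0
      puc <- mean(!is.na(px[is.na(ty)]))
      if (max(cval, crind) >= mincor && puc >= minpuc) P[tv, pv] <- TRUE
    }
    P[tv, intersect(forced, setdiff(num, tv))] <- TRUE
    P[tv, tv] <- FALSE
  }
  P
}

# Bayesian linear regression draw + predictive mean matching for one
# variable (type-1 matching: donors ranked by |yhat_obs(beta_hat) -
# yhat_mis(beta_star)|).
pmm_impute_one <- function(y, X, mis, donors) {
  obs <- !mis
  Xo <- cbind(1, X[obs, , drop = FALSE])
  yo <- y[obs]
  p <- ncol(Xo)
  # ridge epsilon keeps the draw defined under near-collinearity
  XtX <- crossprod(Xo) + diag(1e-5, p)
  XtXinv <- solve(XtX)
  beta_hat <- drop(XtXinv %*% crossprod(Xo, yo))
  res <- yo - drop(Xo %*% beta_hat)
  df <- max(length(yo) - p, 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  beta_star <- beta_hat +
    drop(chol(XtXinv) %*% rnorm(p)) * sqrt(sigma2_star)
  yhat_obs <- drop(Xo %*% beta_hat)
  Xm <- cbind(1, X[mis, , drop = FALSE])
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    cand <- order(d)[seq_len(min(donors, length(d)))]
    yo[cand[sample.int(length(cand), 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with PMM
#'
#' Fills each incomplete variable by iterated regression on its selected
#' predictors with predictive-mean-matching draws: a Bayesian regression
#' draw perturbs the coefficients, the `donors` observed values with closest
#' predictions form the donor pool, and one donor is sampled. Every imputed
#' cell therefore equals a value observed elsewhere in the same column. The
#' `m` imputations are independent chains; the whole procedure is
#' deterministic given `seed`.
#'
#' @param data data frame with missing values in numeric covariates.
#' @param predictor_matrix logical matrix from [quickpred()]; defaults to
#'   `quickpred(data)`.
#' @param m number of imputations.
#' @param maxit chained-equation iterations per imputation.
#' @param donors donor-pool size.
#' @param seed integer seed.
#' @return An object of class `"imputation_set"`: `imputations` (list of m
#'   completed tibbles), the predictor matrix, and the run parameters.
#' @export
mice_pmm <- function(data, predictor_matrix = NULL, m = 20, maxit = 50,
                     donors = 5, seed = 1L) {
  stop_if_not_df(data)
  P <- predictor_matrix %||% quickpred(data)
  targets <- rownames(P)
  if (length(targets)) {
    # visit in order of increasing missingness
    nmiss <- vapply(targets, function(v) sum(is.na(data[[v]])), 0)
    targets <- targets[order(nmiss)]
    for (v in targets) {
      nobs <- sum(!is.na(data[[v]]))
      if (nobs < donors) {
        abort(sprintf("'%s' has %d observed values; at least %d donors are required",
                      v, nobs, donors))
      }
    }
  }
  imps <- withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      comp <- as_tibble(data)
      # initialize missing cells by random draws from the observed values
      for (v in targets) {
        mis <- is.na(comp[[v]])
        obs_vals <- comp[[v]][!mis]
        comp[[v]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
      }
      if (length(targets)) {
        for (it in seq_len(maxit)) {
          for (v in targets) {
            mis <- is.na(data[[v]])
            if (!any(mis)) next
            preds <- colnames(P)[P[v, ]]
            if (!length(preds)) {
              # intercept-only model: PMM reduces to a random draw from a
              # posterior-perturbed mean match
              Xv <- matrix(0, nrow(comp), 0)
            } else {
              Xv <- as.matrix(comp[preds])
            }
            comp[[v]][mis] <- pmm_impute_one(data[[v]], Xv, mis, donors)
          }
        }
      }
      comp
    })
  })
  structure(list(imputations = imps, predictor_matrix = P, m = m,
                 maxit = maxit, donors = donors, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d, maxit = %d, donors = %d, seed = %d\n",
              x$m, x$maxit, x$donors, x$seed))
  cat("  imputed variables:",
      paste(rownames(x$predictor_matrix), collapse = ", "), "\n")
  invisible(x)
}

#' Pool fits across imputations by Rubin's rules
#'
#' Combines m repeated-analysis fits: pooled estimate Qbar (mean), within
#' variance Wbar (mean squared SE), between variance B (sample variance of
#' estimates), total variance T = Wbar + (1 + 1/m) B, Barnard-Rubin
#' small-sample degrees of freedom, and t-based p-values.
#'
#' @param fits list of `tobit_fit` objects (or any objects with a `tidy()`
#'   method returning `term`/`estimate`/`std.error` plus `n` elements) fitted
#'   on the m completed datasets with identical covariate sets.
#' @return An object of class `"pooled_fit"`; `tidy()` returns the pooled
#'   table (`term`, `estimate`, `std.error`, `statistic`, `df`, `p.value`,
#'   `w_bar`, `b_between`).
#' @export
#' @examples
#' # two imputations, hand-checkable pooling arithmetic
#' f <- list(
#'   structure(list(terms = "x", coefficients = c(x = 1), se = c(x = sqrt(0.5)),
#'                  statistic = c(x = 1), p_value = c(x = 0.3), n = 100),
#'             class = "tobit_fit"),
#'   structure(list(terms = "x", coefficients = c(x = 2), se = c(x = sqrt(0.5)),
#'                  statistic = c(x = 2), p_value = c(x = 0.1), n = 100),
#'             class = "tobit_fit"))
#' tidy(pool_rubin(f))  # Qbar 1.5, T = 0.5 + 1.5 * 0.5 = 1.25
pool_rubin <- function(fits) {
  if (!length(fits)) abort("`fits` must be a nonempty list")
  m <- length(fits)
  tabs <- lapply(fits, tidy)
  terms <- tabs[[1]]$term
  for (t in tabs[-1]) {
    if (!identical(t$term, terms)) {
      abort("all fits must share an identical covariate set")
    }
  }
  est <- vapply(tabs, function(t) t$estimate, numeric(length(terms)))
  ses <- vapply(tabs, function(t) t$std.error, numeric(length(terms)))
  est <- matrix(est, nrow = length(terms))
  ses <- matrix(ses, nrow = length(terms))
  qbar <- rowMeans(est)
  wbar <- rowMeans(ses^2)
  if (m == 1) {
    warn("a single fit: between-imputation variance is undefined and set to 0")
    b <- rep(0, length(terms))
  } else {
    b <- apply(est, 1, var)
  }
  tvar <- wbar + (1 + 1 / m) * b
  # Barnard-Rubin adjusted degrees of freedom
  n <- fits[[1]]$n %||% Inf
  k <- length(terms)
  nu_com <- max(n - k, 1)
  lam <- pmin(pmax((1 + 1 / m) * b / tvar, 1e-12), 1 - 1e-12)
  nu_old <- (m - 1) / lam^2
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lam)
  df <- nu_old * nu_obs / (nu_old + nu_obs)
  if (m == 1) df <- rep(nu_com, length(terms))
  stat <- qbar / sqrt(tvar)
  structure(
    list(table = tibble(term = terms, estimate = qbar,
                        std.error = sqrt(tvar), statistic = stat,
                        df = df, p.value = 2 * pt(-abs(stat), df),
                        w_bar = wbar, b_between = b),
         m = m),
    class = "pooled_fit")
}

#' @export
tidy.pooled_fit <- function(x, scale = 1, ...) {
  out <- x$table
  out$estimate <- out$estimate * scale
  out$std.error <- out$std.error * scale
  out
}

#' @export
glance.pooled_fit <- function(x, ...) {
  tibble(m = x$m, n_terms = nrow(x$table))
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled_fit> Rubin's rules over m = %d imputations\n", x$m))
  print(x$table, ...)
  invisible(x)
}

# Backward elimination on one completed dataset: iteratively drop the
# highest-p covariate (ties broken by column order: first of the tied set)
# until all p <= alpha or no covariate remains.
backward_eliminate_one <- function(data, response, candidates, alpha,
                                   lower, upper) {
  current <- candidates
  while (length(current)) {
    fit <- fit_tobit(data[[response]], data[current],
                     lower = lower, upper = upper)
    pv <- fit$p_value[-1]           # drop intercept
    worst <- max(pv)
    if (worst <= alpha) break
    drop_idx <- which(pv >= worst - 1e-12)[1]
    current <- current[-drop_idx]
  }
  current
}

#' Backward elimination across multiply imputed datasets
#'
#' Runs p-value-based backward elimination (cut-off `alpha`) separately
#' within each completed dataset, then retains the covariates selected in at
#' least `retain_frac` of the m datasets. The final model is refit on every
#' dataset and pooled by [pool_rubin()]. An empty final model is a reported
#' outcome, not an error.
#'
#' @param imputation_set a [mice_pmm()] result.
#' @param response response column (present in every completed dataset).
#' @param candidates candidate covariate columns.
#' @param alpha elimination cut-off.
#' @param retain_frac retention threshold across datasets.
#' @param lower,upper Tobit censoring bounds.
#' @return An object of class `"mi_selection"`: `selected`, `counts`
#'   (tibble: variable, n_selected, retained), and `pooled` (a
#'   `pooled_fit`, `NULL` when the final model is empty).
#' @export
stepwise_backward_mi <- function(imputation_set, response, candidates,
                                 alpha = 0.05, retain_frac = 0.5,
                                 lower = 0, upper = 1) {
  if (!inherits(imputation_set, "imputation_set")) {
    abort("`imputation_set` must come from mice_pmm()")
  }
  imps <- imputation_set$imputations
  m <- length(imps)
  for (d in imps) check_cols(d, c(response, candidates), "imputations")
  sel_list <- lapply(imps, backward_eliminate_one, response = response,
                     candidates = candidates, alpha = alpha,
                     lower = lower, upper = upper)
  counts <- vapply(candidates, function(v) {
    sum(vapply(sel_list, function(s) v %in% s, TRUE))
  }, 0)
  need <- ceiling(retain_frac * m)
  selected <- candidates[counts >= need]
  pooled <- NULL
  if (length(selected)) {
    fits <- lapply(imps, function(d) {
      fit_tobit(d[[response]], d[selected], lower = lower, upper = upper)
    })
    pooled <- pool_rubin(fits)
  }
  structure(
    list(selected = selected,
         counts = tibble(variable = candidates, n_selected = unname(counts),
                         retained = unname(counts >= need)),
         threshold = need, m = m, alpha = alpha,
         pooled = pooled),
    class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat(sprintf("<mi_selection> backward elimination (alpha = %g) over m = %d datasets; retained when selected in >= %d\n",
              x$alpha, x$m, x$threshold))
  cat("  final model:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(empty)",
      "\n")
  invisible(x)
}

#' @export
tidy.mi_selection <- function(x, ...) x$counts
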