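# Synthetic cohort generation: Gaussian copula with calibrated latent
# correlations and per-variable marginal transforms.

# Resolve derived parameters once per marginal (truncated-normal parent
# parameters are found by moment matching, which is too slow to redo per
# quantile call during copula calibration).
resolve_marginal <- function(spec) {
  if (spec$dist == "truncnorm" && is.null(spec$mu)) {
    par <- solve_truncnorm(spec$mean, spec$sd, spec$lower, spec$upper)
    spec$mu <- par[["mu"]]
    spec$sigma <- par[["sigma"]]
  }
  spec
}

# Quantile transform of a copula uniform u into the marginal distribution.
# u is clamped away from 0/1 so unbounded margins stay finite even for
# latent draws (or quadrature nodes) beyond double-precision tail support.
q_marginal <- function(u, spec) {
  u <- pmin(pmax(u, 1e-16), 1 - 1e-16)
  switch(spec$dist,
    truncnorm = {
      spec <- resolve_marginal(spec)
      qtruncnorm_(u, spec$mu, spec$sigma, spec$lower, spec$upper)
    },
    lognorm = {
      pcap <- plnorm(spec$upper, spec$meanlog, spec$sdlog)
      qlnorm(u * pcap, spec$meanlog, spec$sdlog)
    },
    zi_lognorm = {
      p0 <- 1 - spec$prevalence
      out <- numeric(length(u))
      nz <- u > p0
      if (any(nz)) {
        v <- (u[nz] - p0) / spec$prevalence
        pcap <- plnorm(spec$upper, spec$meanlog, spec$sdlog)
        out[nz] <- qlnorm(v * pcap, spec$meanlog, spec$sdlog)
      }
      out
    },
    binary = as.numeric(u > 1 - spec$p),
    abort(sprintf("unknown marginal distribution '%s'", spec$dist))
  )
}

# Moments of a marginal under its quantile transform, by quadrature on the
# latent normal scale.
marginal_moments_gh <- function(spec, gh) {
  if (spec$dist == "binary") {
    return(c(mean = spec$p, sd = sqrt(spec$p * (1 - spec$p))))
  }
  x <- q_marginal(pnorm(gh$nodes), spec)
  m <- sum(gh$weights * x)
  v <- sum(gh$weights * (x - m)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Realized Pearson correlation between two transformed margins when the
# latent Gaussian correlation is rho (2-D Gauss-Hermite quadrature).
realized_pearson <- function(rho, spec1, spec2, gh) {
  # put a binary margin (a step function, which Gauss-Hermite integrates
  # poorly) on the inner, analytically tractable side
  if (spec1$dist == "binary" && spec2$dist != "binary") {
    tmp <- spec1; spec1 <- spec2; spec2 <- tmp
  }
  m1 <- marginal_moments_gh(spec1, gh)
  m2 <- marginal_moments_gh(spec2, gh)
  z1 <- gh$nodes
  f1 <- q_marginal(pnorm(z1), spec1)
  s <- sqrt(1 - rho^2)
  if (spec2$dist == "binary") {
    # E[1{U2 > 1 - p} | z1] = P(z2 > qnorm(1 - p) | z1), exactly
    thr <- qnorm(1 - spec2$p)
    ez2 <- pnorm((rho * z1 - thr) / s)
  } else {
    # z2 | z1 ~ N(rho z1, 1 - rho^2); integrate over the conditional
    ez2 <- vapply(z1, function(z) {
      sum(gh$weights * q_marginal(pnorm(rho * z + s * gh$nodes), spec2))
    }, numeric(1))
  }
  exy <- sum(gh$weights * f1 * ez2)
  (exy - m1[["mean"]] * m2[["mean"]]) / (m1[["sd"]] * m2[["sd"]])
}

# Latent rho such that the realized Pearson correlation equals target.
# Monotone in rho, so a plain root find suffices.
calibrate_latent_rho <- function(target, spec1, spec2, gh = NULL) {
  gh <- gh %||% gauss_hermite_normal(96)
  f <- function(rho) realized_pearson(rho, spec1, spec2, gh) - target
  lo <- -0.995
  hi <- 0.995
  flo <- f(lo)
  fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "correlation target %.3f is outside the attainable range [%.3f, %.3f] for this pair",
      target, flo + target, fhi + target))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-5)$root
}

# Assemble the latent correlation matrix: calibrate each configured pair,
# then repair to the nearest PSD correlation matrix if necessary. Memoized on
# the (marginals, correlations) pair since calibration is deterministic.
latent_cache <- new.env(parent = emptyenv())
build_latent_correlation <- function(marginals, correlations) {
  key <- rlang::hash(list(marginals, correlations))
  hit <- latent_cache[[key]]
  if (!is.null(hit)) return(hit)
  marginals <- lapply(marginals, resolve_marginal)
  vars <- names(marginals)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  if (nrow(correlations)) {
    gh <- gauss_hermite_normal(96)
    for (k in seq_len(nrow(correlations))) {
      v1 <- correlations$var1[k]
      v2 <- correlations$var2[k]
      rho <- calibrate_latent_rho(correlations$r[k],
                                  marginals[[v1]], marginals[[v2]], gh)
      R[v1, v2] <- rho
      R[v2, v1] <- rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    rep <- Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE,
                          eig.tol = 1e-8, posd.tol = 1e-8)
    R2 <- as.matrix(rep$mat)
    if (!rep$converged ||
        min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      abort("correlation targets do not admit a positive semi-definite latent matrix, even after nearest-PSD repair")
    }
    shift <- max(abs(R2 - R))
    if (shift > 0.05) {
      warn(sprintf(
        "nearest-PSD repair moved latent correlations by up to %.3f; realized correlations may deviate from targets", shift))
    }
    dimnames(R2) <- dimnames(R)
    R <- R2
  }
  latent_cache[[key]] <- R
  R
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants from a Gaussian copula whose latent correlations are
#' calibrated so the realized Pearson correlations between generated columns
#' match the configured targets, then maps each latent coordinate through its
#' marginal quantile transform (truncated normal for lifestyle and nutrient
#' intakes, zero-inflated log-normal for genus relative abundances and
#' episodic behaviours, Bernoulli for indicators). Deterministic given the
#' config's seed.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per participant: `participant_id` plus every
#'   configured variable. Genus abundances are relative abundances in
#'   permille, bounded to `[0, 1000]`; DEA input/output columns contain no
#'   missing values.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 30, seed = 7))
#' mean(cohort$streptococcus > 0)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config()")
  }
  vars <- names(config$marginals)
  R <- build_latent_correlation(config$marginals, config$correlations)
  n <- config$n
  if (n == 0L) {
    cols <- c(list(participant_id = integer()),
              setNames(rep(list(numeric()), length(vars)), vars))
    return(as_tibble(cols))
  }
  U <- withr::with_seed(config$seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = R)
    pnorm(matrix(Z, nrow = n))
  })
  colnames(U) <- vars
  out <- lapply(vars, function(v) q_marginal(U[, v], config$marginals[[v]]))
  names(out) <- vars
  dplyr::bind_cols(tibble(participant_id = seq_len(n)), as_tibble(out))
}

#' Inject missing values completely at random
#'
#' Sets exactly the requested number of cells to `NA` in each covariate
#' column, sampling rows without replacement. DEA input/output columns are
#' protected: the lifestyle inputs and microbiota outputs must stay complete
#' for the frontier analysis, so missingness is only allowed in covariates.
#'
#' @param table a cohort table (e.g. from [generate_cohort()]).
#' @param counts named integer vector: number of cells to blank per column.
#' @param seed integer RNG seed.
#' @return The table with `NA`s injected, as a tibble.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 20, seed = 1))
#' withna <- inject_missingness(cohort, c(bmi = 3), seed = 2)
#' sum(is.na(withna$bmi))
inject_missingness <- function(table, counts, seed = 1L) {
  stop_if_not_df(table)
  if (length(counts) == 0) return(as_tibble(table))
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be a named vector")
  }
  check_cols(table, names(counts), "table")
  dea_cols <- c(dea_input_candidates(), dea_output_candidates())
  hit <- intersect(names(counts), dea_cols)
  if (length(hit)) {
    abort(sprintf("cannot inject missingness into DEA column(s): %s",
                  paste(hit, collapse = ", ")))
  }
  n <- nrow(table)
  if (any(counts < 0) || any(counts > n)) {
    abort(sprintf("each missingness count must be in [0, %d]", n))
  }
  out <- as_tibble(table)
  withr::with_seed(seed, {
    for (v in names(counts)) {
      k <- counts[[v]]
      if (k > 0) {
        rows <- sample.int(n, k)
        out[[v]][rows] <- NA
      }
    }
  })
  out
}

#' Write / read a cohort with provenance
#'
#' The cohort is stored as a UTF-8 CSV with a header row; an adjacent
#' `<path>.provenance.json` records the seed and generation parameters so a
#' run can be reproduced from its artifacts.
#'
#' @param table cohort tibble.
#' @param path CSV path.
#' @param config optional [cohort_config()] used to generate the table.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a tibble.
#' @export
write_cohort <- function(table, path, config = NULL) {
  readr::write_csv(table, path, na = "")
  prov <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n = nrow(table),
    columns = names(table))
  if (!is.null(config)) {
    prov$seed <- config$seed
    prov$missingness <- as.list(config$missingness)
  }
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
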