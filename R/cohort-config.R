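#' Marginal distribution specifications for the synthetic cohort
#'
#' Constructors for the per-variable marginal specifications consumed by
#' [cohort_config()]. Four families cover the cohort's variables:
#'
#' * `marg_truncnorm()` — a normal with given mean/sd truncated to
#'   `[lower, upper]`. The parent parameters are re-solved at generation time
#'   so that the *realized* (post-truncation) mean and sd match the request.
#' * `marg_lognorm()` — a log-normal, parameterized either directly
#'   (`meanlog`, `sdlog`) or through `median`/`q25`/`q75` (quartile matching)
#'   or `mean`/`sd` (moment matching).
#' * `marg_zi_lognorm()` — a zero-inflated log-normal: value 0 with
#'   probability `1 - prevalence`, otherwise log-normal. Used for genus
#'   relative abundances (structural zeros below the detection limit) and for
#'   behaviours many participants do not engage in (alcohol, smoking, MVPA).
#'   When parameterized by `mean`/`sd` these are the *overall* moments
#'   (zeros included).
#' * `marg_binary()` — a 0/1 indicator with success probability `p`.
#'
#' @param mean,sd target mean and standard deviation.
#' @param lower,upper truncation bounds (`lower < upper`).
#' @param meanlog,sdlog log-scale location and scale.
#' @param median,q25,q75 quartiles of the (nonzero part of the) distribution.
#' @param prevalence probability of a nonzero value, in `[0, 1]`.
#' @param p success probability of the indicator, in `[0, 1]`.
#'
#' @return A list with class `"gutdea_marginal"` describing the marginal.
#' @name marginals
NULL

#' @rdname marginals
#' @export
marg_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is_number(mean), is_number(sd), sd > 0, lower < upper)
  structure(list(dist = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "gutdea_marginal")
}

#' @rdname marginals
#' @export
marg_lognorm <- function(meanlog = NULL, sdlog = NULL, median = NULL,
                         q25 = NULL, q75 = NULL, mean = NULL, sd = NULL,
                         upper = Inf) {
  par <- lognorm_params(meanlog, sdlog, median, q25, q75, mean, sd, p = 1)
  structure(list(dist = "lognorm", meanlog = par[["meanlog"]],
                 sdlog = par[["sdlog"]], upper = upper),
            class = "gutdea_marginal")
}

#' @rdname marginals
#' @export
marg_zi_lognorm <- function(prevalence, meanlog = NULL, sdlog = NULL,
                            median = NULL, q25 = NULL, q75 = NULL,
                            mean = NULL, sd = NULL, upper = Inf) {
  stopifnot(is_number(prevalence), prevalence >= 0, prevalence <= 1)
  par <- lognorm_params(meanlog, sdlog, median, q25, q75, mean, sd,
                        p = prevalence)
  structure(list(dist = "zi_lognorm", prevalence = prevalence,
                 meanlog = par[["meanlog"]], sdlog = par[["sdlog"]],
                 upper = upper),
            class = "gutdea_marginal")
}

#' @rdname marginals
#' @export
marg_binary <- function(p) {
  stopifnot(is_number(p), p >= 0, p <= 1)
  structure(list(dist = "binary", p = p), class = "gutdea_marginal")
}

# Resolve a log-normal parameterization. Quartile matching: meanlog =
# log(median), sdlog = log(q75/q25) / (2 * qnorm(0.75)). Moment matching for a
# zero-inflated log-normal with nonzero probability p and overall moments
# (M, S): exp(sdlog^2) = p (S^2 + M^2) / M^2, meanlog = log(M / p) - sdlog^2/2.
lognorm_params <- function(meanlog, sdlog, median, q25, q75, mean, sd, p) {
  if (!is.null(meanlog) && !is.null(sdlog)) {
    stopifnot(is_number(meanlog), is_number(sdlog), sdlog > 0)
    return(c(meanlog = meanlog, sdlog = sdlog))
  }
  if (!is.null(median) && !is.null(q25) && !is.null(q75)) {
    stopifnot(q25 > 0, q25 < q75, median >= q25, median <= q75)
    return(c(meanlog = log(median),
             sdlog = log(q75 / q25) / (2 * qnorm(0.75))))
  }
  if (!is.null(mean) && !is.null(sd)) {
    stopifnot(mean > 0, sd > 0, p > 0)
    s2 <- log(p * (sd^2 + mean^2) / mean^2)
    if (s2 <= 0) {
      abort(sprintf(
        "mean %g, sd %g at prevalence %g cannot be matched by a %slog-normal",
        mean, sd, p, if (p < 1) "zero-inflated " else ""))
    }
    return(c(meanlog = log(mean / p) - s2 / 2, sdlog = sqrt(s2)))
  }
  abort("supply meanlog+sdlog, median+q25+q75, or mean+sd")
}

# Column roles used for validation and default variable sets.
dea_input_candidates <- function() {
  c("mufa_g", "n3pufa_g", "n6pufa_g", "fiber_sol_g", "fiber_insol_g",
    "alcohol_units", "cigarettes_day", "mvpa_met_h", "sleep_h")
}
dea_output_candidates <- function() {
  c("bacillus", "bifidobacterium", "lactobacillus", "lactococcus",
    "streptococcus", "fpd")
}
genus_columns <- function() {
  c("bacillus", "bifidobacterium", "lactobacillus", "lactococcus",
    "streptococcus")
}
tobit_covariate_columns <- function() {
  c("age", "sex_female", "bmi", "egfr", "hb", "bun", "hba1c", "energy_kcal",
    "fat_g", "salt_g", "ffq_yogurt", "ffq_natto", "ffq_seaweed",
    "ffq_fried_food", "ffq_coffee", "antibiotics", "probiotics")
}

# Default marginals: a 577-participant Japanese population-based cohort.
# Continuous lifestyle/nutrient variables are truncated normals matched to the
# published mean (SD); genus relative abundances (permille) are zero-inflated
# log-normals matched to the nonzero median (IQR) and the nonzero prevalence;
# food-frequency items are log-normals matched to median (IQR); alcohol,
# smoking and MVPA are zero-inflated log-normals matched to the overall
# mean (SD) at a realistic engagement prevalence. Abundances are capped at
# 1000 permille; alcohol and cigarettes are capped just below the inversion
# pivots (5.5 units, 90 cigarettes) so the detrimental-input inversion is
# always defined.
default_marginals <- function() {
  list(
    age            = marg_truncnorm(58.6, 14.6, lower = 21, upper = 84),
    sex_female     = marg_binary(366 / 577),
    bmi            = marg_truncnorm(22.6, 3.1, lower = 13, upper = 45),
    egfr           = marg_truncnorm(75.4, 16.0, lower = 10, upper = 140),
    hb             = marg_truncnorm(13.9, 1.4, lower = 7, upper = 20),
    bun            = marg_lognorm(mean = 20.7, sd = 30.4),
    hba1c          = marg_truncnorm(5.60, 0.53, lower = 4, upper = 13),
    energy_kcal    = marg_truncnorm(1545, 437, lower = 0),
    fat_g          = marg_truncnorm(47.8, 12.0, lower = 0),
    sfa_g          = marg_truncnorm(12.1, 3.1, lower = 0),
    mufa_g         = marg_truncnorm(17.2, 4.4, lower = 0),
    n3pufa_g       = marg_truncnorm(2.2, 0.6, lower = 0),
    n6pufa_g       = marg_truncnorm(10.9, 3.0, lower = 0),
    fiber_sol_g    = marg_truncnorm(2.1, 0.7, lower = 0),
    fiber_insol_g  = marg_truncnorm(8.2, 2.3, lower = 0),
    salt_g         = marg_truncnorm(4.4, 1.3, lower = 0),
    alcohol_units  = marg_zi_lognorm(0.35, mean = 0.3, sd = 0.7, upper = 5.4),
    cigarettes_day = marg_zi_lognorm(188 / 577, mean = 5.3, sd = 10.1,
                                     upper = 89),
    mvpa_met_h     = marg_zi_lognorm(0.85, mean = 12.0, sd = 10.6),
    sleep_h        = marg_truncnorm(6.5, 1.0, lower = 0, upper = 24),
    ffq_yogurt     = marg_lognorm(median = 0.2, q25 = 0.1, q75 = 1.0),
    ffq_natto      = marg_lognorm(median = 0.2, q25 = 0.1, q75 = 0.5),
    ffq_seaweed    = marg_lognorm(median = 0.2, q25 = 0.1, q75 = 0.5),
    ffq_fried_food = marg_lognorm(median = 0.2, q25 = 0.1, q75 = 0.2),
    ffq_coffee     = marg_lognorm(median = 1.0, q25 = 0.5, q75 = 2.0),
    antibiotics    = marg_binary(3 / 577),
    probiotics     = marg_binary(15 / 577),
    bacillus       = marg_zi_lognorm(208 / 577, median = 1.81, q25 = 0.78,
                                     q75 = 3.09, upper = 1000),
    bifidobacterium = marg_zi_lognorm(166 / 577, median = 20, q25 = 5,
                                      q75 = 80, upper = 1000),
    lactobacillus  = marg_zi_lognorm(236 / 577, median = 1.33, q25 = 0.37,
                                     q75 = 6.74, upper = 1000),
    lactococcus    = marg_zi_lognorm(86 / 577, median = 0.31, q25 = 0.16,
                                     q75 = 0.88, upper = 1000),
    streptococcus  = marg_zi_lognorm(569 / 577, median = 6.46, q25 = 2.28,
                                     q75 = 20.33, upper = 1000),
    fpd            = marg_truncnorm(30.8, 7.9, lower = 0)
  )
}

# Default correlation targets (realized Pearson scale, on the generated raw
# columns). Input-output entries follow the published screening grid; the
# detrimental behaviours (alcohol, smoking) appear there on the inverted
# scale, so their signs are flipped here. Nutrient-nutrient and
# covariate-covariate entries encode ordinary dietary/physiological structure
# and are the package's own realistic defaults.
default_correlations <- function() {
  tribble_cor <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(var1 = m[, 1], var2 = m[, 2], r = as.numeric(m[, 3]))
  }
  # Raw-scale Pearson correlations between two zero-inflated heavy-tailed
  # margins are bounded well inside (-1, 1); the published alcohol x genus
  # values (measured on the study's transformed scale) exceed that bound on
  # the raw permille scale, so those two targets use the nearest
  # attainable magnitude.
  tribble_cor(
    "alcohol_units", "streptococcus", -0.15,
    "alcohol_units", "bacillus",      -0.08,
    "alcohol_units", "lactobacillus", -0.06,
    "sleep_h",       "streptococcus",  0.22,
    "sleep_h",       "bacillus",       0.08,
    "sleep_h",       "lactobacillus",  0.09,
    "fiber_sol_g",   "bacillus",       0.15,
    "fiber_sol_g",   "streptococcus",  0.13,
    "fiber_sol_g",   "lactococcus",    0.09,
    "fiber_sol_g",   "fpd",            0.18,
    "n3pufa_g",      "bifidobacterium", -0.11,
    "n3pufa_g",      "fpd",            0.09,
    "fiber_insol_g", "lactobacillus", -0.09,
    "mvpa_met_h",    "lactobacillus",  0.08,
    "energy_kcal",   "fat_g",          0.60,
    "energy_kcal",   "sfa_g",          0.50,
    "energy_kcal",   "mufa_g",         0.55,
    "energy_kcal",   "n3pufa_g",       0.40,
    "energy_kcal",   "n6pufa_g",       0.50,
    "energy_kcal",   "fiber_sol_g",    0.40,
    "energy_kcal",   "fiber_insol_g",  0.45,
    "energy_kcal",   "salt_g",         0.50,
    "energy_kcal",   "sex_female",    -0.30,
    "fat_g",         "sfa_g",          0.70,
    "fat_g",         "mufa_g",         0.70,
    "fat_g",         "n6pufa_g",       0.60,
    "fat_g",         "n3pufa_g",       0.30,
    "fat_g",         "fiber_sol_g",    0.20,
    "fat_g",         "fiber_insol_g",  0.25,
    "fat_g",         "salt_g",         0.35,
    "sfa_g",         "mufa_g",         0.60,
    "sfa_g",         "n3pufa_g",       0.20,
    "sfa_g",         "n6pufa_g",       0.35,
    "sfa_g",         "fiber_sol_g",    0.18,
    "sfa_g",         "fiber_insol_g",  0.22,
    "sfa_g",         "salt_g",         0.30,
    "mufa_g",        "n3pufa_g",       0.25,
    "mufa_g",        "n6pufa_g",       0.50,
    "mufa_g",        "fiber_sol_g",    0.20,
    "mufa_g",        "fiber_insol_g",  0.25,
    "mufa_g",        "salt_g",         0.30,
    "n3pufa_g",      "n6pufa_g",       0.30,
    "n3pufa_g",      "fiber_sol_g",    0.20,
    "n3pufa_g",      "fiber_insol_g",  0.25,
    "n3pufa_g",      "salt_g",         0.25,
    "n6pufa_g",      "fiber_sol_g",    0.20,
    "n6pufa_g",      "fiber_insol_g",  0.25,
    "n6pufa_g",      "salt_g",         0.30,
    "fiber_sol_g",   "fiber_insol_g",  0.60,
    "fiber_sol_g",   "salt_g",         0.25,
    "fiber_insol_g", "salt_g",         0.30,
    "sex_female",    "fat_g",         -0.18,
    "sex_female",    "salt_g",        -0.15,
    "age",           "egfr",          -0.50,
    "age",           "hba1c",          0.25,
    "bmi",           "hba1c",          0.30,
    "sex_female",    "hb",            -0.45,
    "ffq_yogurt",    "bifidobacterium", 0.10
  )
}

# Default number of missing values per covariate (at the reference n = 577).
default_missingness <- function() {
  c(bmi = 8L, egfr = 40L, hba1c = 27L, hb = 29L)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles everything [generate_cohort()] needs: cohort size, RNG seed,
#' per-variable marginal specifications, pairwise correlation targets and the
#' per-covariate missingness counts. The defaults emulate a 577-participant
#' population-based cohort with fecal 16S profiling: published mean (SD) or
#' median (IQR) marginals, genus-level zero-inflation, and the published
#' input-output correlation structure.
#'
#' @param n number of participants (non-negative integer).
#' @param seed integer RNG seed; the generator is deterministic given the
#'   config.
#' @param marginals named list of [marginals] specifications; defaults cover
#'   all cohort variables.
#' @param correlations data frame with columns `var1`, `var2`, `r`: target
#'   *realized* Pearson correlations between generated columns. Latent copula
#'   correlations are calibrated so the realized values match these targets;
#'   the assembled latent matrix is repaired to the nearest positive
#'   semi-definite correlation matrix if needed.
#' @param missingness named integer vector of missing-value counts per
#'   covariate (applied by [inject_missingness()]; never on DEA columns).
#' @param female_fraction convenience override for the `sex_female` marginal.
#'
#' @return An object of class `"cohort_config"`.
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
#' @examples
#' cfg <- cohort_config(n = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' dim(cohort)
cohort_config <- function(n = 577, seed = 1L,
                          marginals = default_marginals(),
                          correlations = default_correlations(),
                          missingness = default_missingness(),
                          female_fraction = NULL) {
  if (!is_number(n) || n < 0 || n != round(n)) {
    abort("`n` must be a non-negative integer")
  }
  stopifnot(is_number(seed))
  if (!is.null(female_fraction)) {
    marginals$sex_female <- marg_binary(female_fraction)
  }
  if (!all(vapply(marginals, inherits, TRUE, "gutdea_marginal"))) {
    abort("all `marginals` entries must be built with marg_*() constructors")
  }
  stop_if_not_df(correlations, "correlations")
  check_cols(correlations, c("var1", "var2", "r"), "correlations")
  bad <- setdiff(unique(c(correlations$var1, correlations$var2)),
                 names(marginals))
  if (length(bad)) {
    abort(sprintf("correlation targets reference unknown variable(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(abs(correlations$r) >= 1)) {
    abort("correlation targets must lie strictly inside (-1, 1)")
  }
  if (length(missingness)) {
    if (is.null(names(missingness)) || any(!nzchar(names(missingness)))) {
      abort("`missingness` must be a named vector")
    }
    dea_cols <- c(dea_input_candidates(), dea_output_candidates())
    hit <- intersect(names(missingness), dea_cols)
    if (length(hit)) {
      abort(sprintf("missingness is not allowed on DEA columns: %s",
                    paste(hit, collapse = ", ")))
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marginals,
         correlations = correlations, missingness = missingness),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n:", x$n, " seed:", x$seed, "\n")
  cat("  variables:", length(x$marginals), "\n")
  cat("  correlation targets:", nrow(x$correlations), "\n")
  cat("  missingness:",
      paste(names(x$missingness), x$missingness, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
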