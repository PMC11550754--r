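# Shared fixtures, built in code.

# Small 3-DMU problem whose VRS frontier is the A-B segment; C projects onto
# the midpoint with phi = 1.25.
abc_problem <- function() {
  list(X = matrix(c(1, 3, 2), ncol = 1),
       Y = matrix(c(1, 4, 2), ncol = 1))
}

# Random strictly positive DEA problem.
random_problem <- function(n_dmu, n_in = 2, n_out = 2, lo = 1, hi = 10) {
  list(X = matrix(runif(n_dmu * n_in, lo, hi), n_dmu),
       Y = matrix(runif(n_dmu * n_out, lo, hi), n_dmu))
}

# The worked peer-decomposition example shipped with the package (weights
# and outputs quoted at 3-decimal precision).
worked_example <- function() {
  path <- system.file("extdata", "worked_example_decomposition.csv",
                      package = "gutdea")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out_cols <- c("bacillus", "lactobacillus", "lactococcus",
                "streptococcus", "fpd")
  list(
    raw = tab[tab$kind == "raw", c("peer", "lambda", out_cols)],
    weighted = tab[tab$kind == "weighted", c("peer", "lambda", out_cols)],
    own = unlist(tab[tab$kind == "own", out_cols]),
    sum_weighted = unlist(tab[tab$kind == "sum_weighted", out_cols]),
    lack = unlist(tab[tab$kind == "lack", out_cols]),
    outputs = out_cols)
}

# Small cohort generated once per test file load (kept tiny for speed).
small_cohort <- local({
  memo <- NULL
  function(n = 150, seed = 42) {
    if (is.null(memo)) {
      memo <<- generate_cohort(cohort_config(n = n, seed = seed))
    }
    memo
  }
})

# Simulate two-sided censored regression data with known truth.
simulate_tobit <- function(n, beta = c(0.8, 0.1, -0.05), sigma = 0.05,
                           lower = 0, upper = 1) {
  X <- cbind(x = rnorm(n), z = rnorm(n))
  ystar <- beta[1] + drop(X %*% beta[-1]) + rnorm(n, sd = sigma)
  list(y = pmin(pmax(ystar, lower), upper), x = as.data.frame(X),
       beta = beta, sigma = sigma)
}
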