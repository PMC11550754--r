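# Synthetic cohort generator: marginal fidelity, zero-inflation, copula
# correlation recovery, determinism, missingness injection.

test_that("generator is deterministic and handles the empty cohort", {
  cfg <- cohort_config(n = 40, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 40)

  empty <- generate_cohort(cohort_config(n = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty), names(a))

  expect_error(cohort_config(n = -3), "non-negative")
})

test_that("truncated-normal marginals recover configured mean and sd", {
  ch <- generate_cohort(cohort_config(n = 10000, seed = 2024))
  m <- default_marginals()
  tn_vars <- names(m)[vapply(m, function(s) s$dist == "truncnorm", TRUE)]
  for (v in tn_vars) {
    spec <- m[[v]]
    x <- ch[[v]]
    mc_se_mean <- spec$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - spec$mean), 3 * mc_se_mean,
              label = sprintf("|mean(%s) - %g|", v, spec$mean))
    mc_se_sd <- spec$sd / sqrt(2 * (length(x) - 1))
    expect_lt(abs(sd(x) - spec$sd), 3.5 * mc_se_sd,
              label = sprintf("|sd(%s) - %g|", v, spec$sd))
    expect_gte(min(x), spec$lower)
    expect_lte(max(x), spec$upper)
  }
})

test_that("genus zero-inflation and nonzero quartiles match the config", {
  ch <- generate_cohort(cohort_config(n = 10000, seed = 77))
  m <- default_marginals()
  genera <- c("bacillus", "lactobacillus", "lactococcus", "streptococcus",
              "bifidobacterium")
  for (g in genera) {
    spec <- m[[g]]
    prev_hat <- mean(ch[[g]] > 0)
    # binomial 99% bound on the realized prevalence
    bound <- qnorm(0.995) * sqrt(spec$prevalence * (1 - spec$prevalence) /
                                   nrow(ch))
    expect_lt(abs(prev_hat - spec$prevalence), bound + 1e-9,
              label = sprintf("prevalence(%s)", g))
    nz <- ch[[g]][ch[[g]] > 0]
    expect_lt(abs(log(median(nz)) - spec$meanlog), 0.1,
              label = sprintf("log-median(%s)", g))
    expect_true(all(ch[[g]] >= 0 & ch[[g]] <= 1000))
  }
})

test_that("realized Pearson correlations track configured targets", {
  co <- default_correlations()
  # heavy-tailed margins make single-cohort Pearson estimates noisy (sd up
  # to ~0.02 at n = 10,000), so the check averages three replicates
  reps <- lapply(1:3, function(s) {
    generate_cohort(cohort_config(n = 10000, seed = s))
  })
  for (k in seq_len(nrow(co))) {
    rbar <- mean(vapply(reps, function(ch) {
      cor(ch[[co$var1[k]]], ch[[co$var2[k]]])
    }, numeric(1)))
    expect_lt(abs(rbar - co$r[k]), 0.03,
              label = sprintf("realized r(%s, %s) - %g",
                              co$var1[k], co$var2[k], co$r[k]))
  }
})

test_that("missingness injection is exact, protected, and deterministic", {
  ch <- generate_cohort(cohort_config(n = 577, seed = 5))
  counts <- c(bmi = 8, egfr = 40, hba1c = 27, hb = 29)
  out <- inject_missingness(ch, counts, seed = 11)
  for (v in names(counts)) {
    expect_equal(sum(is.na(out[[v]])), unname(counts[[v]]))
  }
  expect_identical(out, inject_missingness(ch, counts, seed = 11))

  expect_identical(inject_missingness(ch, c(bmi = 0), seed = 1), ch)
  expect_error(inject_missingness(ch, c(bmi = nrow(ch) + 1), seed = 1),
               "must be in")
  expect_error(inject_missingness(ch, c(streptococcus = 2), seed = 1),
               "DEA column")
})

test_that("invalid configurations fail loudly", {
  expect_error(cohort_config(correlations = data.frame(var1 = "age",
                                                       var2 = "nope",
                                                       r = 0.2)),
               "unknown variable")
  expect_error(cohort_config(correlations = data.frame(var1 = "age",
                                                       var2 = "bmi",
                                                       r = 1.0)),
               "inside")
  expect_error(cohort_config(missingness = c(streptococcus = 3)), "DEA")
  expect_error(marg_truncnorm(1, -1), "sd")
  expect_error(marg_zi_lognorm(1.2, meanlog = 0, sdlog = 1), "prevalence")
  # an overdispersed target that no truncated-at-zero normal can match
  expect_error(
    generate_cohort(cohort_config(
      n = 5, marginals = list(a = marg_truncnorm(0.3, 0.7, lower = 0)),
      correlations = data.frame(var1 = character(), var2 = character(),
                                r = numeric()),
      missingness = c())),
    "cannot match")
})

test_that("cohort round-trips through CSV with provenance", {
  cfg <- cohort_config(n = 25, seed = 3)
  ch <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path, cfg)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(ch), tolerance = 1e-12)
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(prov$seed, 3)
  expect_equal(prov$n, 25)
})
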