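# Quickpred predictor selection, chained-equation PMM, Rubin pooling and
# backward elimination across imputations.

test_that("quickpred applies the correlation and usable-cases rules", {
  set.seed(18)
  n <- 400
  a <- rnorm(n)
  strong <- 0.5 * a + sqrt(0.75) * rnorm(n)   # corr ~ 0.5 with a
  weak <- 0.02 * a + rnorm(n)                 # corr ~ 0.02
  d <- data.frame(a = a, strong = strong, weak = weak, f = rnorm(n))
  d$a[sample(n, 80)] <- NA
  P <- quickpred(d, mincor = 0.1, minpuc = 0.25, forced = "f")
  expect_equal(rownames(P), "a")
  expect_true(P["a", "strong"])
  expect_false(P["a", "weak"])
  expect_true(P["a", "f"])                    # forced in regardless
  expect_false(P["a", "a"])

  # fully observed data: nothing to impute
  expect_equal(nrow(quickpred(data.frame(x = 1:10, y = 10:1))), 0)

  dd <- data.frame(x = rep(NA_real_, 5), y = 1:5)
  expect_error(quickpred(dd), "no observed values")
})

test_that("PMM imputations stay on observed support and are reproducible", {
  set.seed(25)
  n <- 300
  a <- rnorm(n)
  b <- 0.7 * a + 0.5 * rnorm(n)
  d <- tibble::tibble(a = a, b = b)
  d$b[sample(n, 70)] <- NA
  imp <- mice_pmm(d, m = 3, maxit = 4, donors = 5, seed = 31)
  for (comp in imp$imputations) {
    expect_false(anyNA(comp))
    expect_true(all(comp$b[is.na(d$b)] %in% d$b[!is.na(d$b)]))
    expect_identical(comp$b[!is.na(d$b)], d$b[!is.na(d$b)])
  }
  imp2 <- mice_pmm(d, m = 3, maxit = 4, donors = 5, seed = 31)
  expect_identical(imp$imputations, imp2$imputations)
  imp3 <- mice_pmm(d, m = 1, maxit = 1, donors = 5, seed = 31)
  expect_identical(imp3$imputations[[1]],
                   mice_pmm(d, m = 1, maxit = 1, donors = 5,
                            seed = 31)$imputations[[1]])

  dd <- tibble::tibble(x = c(1, 2, 3, NA, NA), y = rnorm(5))
  expect_error(mice_pmm(dd, donors = 5), "donors")
})

test_that("MCAR deletion is recovered to within sampling error", {
  set.seed(61)
  n <- 1000
  a <- rnorm(n)
  b <- 2 + 0.8 * a + rnorm(n, sd = 0.6)
  full <- tibble::tibble(a = a, b = b)
  holed <- full
  holed$b[sample(n, 250)] <- NA
  imp <- mice_pmm(holed, m = 5, maxit = 8, donors = 5, seed = 7)
  means <- vapply(imp$imputations, function(t) mean(t$b), numeric(1))
  se <- sd(full$b) / sqrt(n)
  expect_lt(abs(mean(means) - mean(full$b)), 3 * se)
})

test_that("Rubin pooling reproduces the stated identities", {
  mk <- function(est, se2) {
    structure(list(terms = "x", coefficients = c(x = est),
                   se = c(x = sqrt(se2)), statistic = c(x = 0),
                   p_value = c(x = 1), n = 100),
              class = "tobit_fit")
  }
  pooled <- pool_rubin(list(mk(1.0, 0.5), mk(2.0, 0.5)))
  tab <- pooled$table
  expect_equal(tab$estimate, 1.5)
  expect_equal(tab$w_bar, 0.5)
  expect_equal(tab$b_between, 0.5)
  expect_equal(tab$std.error^2, 0.5 + (1 + 1 / 2) * 0.5)  # T = 1.25

  # identical fits: B = 0, T = W
  same <- pool_rubin(list(mk(1.3, 0.4), mk(1.3, 0.4), mk(1.3, 0.4)))
  expect_equal(same$table$b_between, 0)
  expect_equal(same$table$std.error^2, 0.4)

  # single fit: warn, T = W
  expect_warning(one <- pool_rubin(list(mk(1.1, 0.2))), "single")
  expect_equal(one$table$std.error^2, 0.2)

  bad <- structure(list(terms = "zz", coefficients = c(zz = 1),
                        se = c(zz = 1), statistic = c(zz = 0),
                        p_value = c(zz = 1), n = 100),
                   class = "tobit_fit")
  expect_error(pool_rubin(list(mk(1, 1), bad)), "identical covariate set")

  # pooled variance never below the within component
  expect_true(all(tab$std.error^2 >= tab$w_bar))
})

test_that("backward elimination keeps the real signal and drops noise", {
  set.seed(91)
  n <- 500
  x1 <- rnorm(n)
  noise <- matrix(rnorm(n * 4), n)
  colnames(noise) <- paste0("n", 1:4)
  y <- pmin(pmax(0.75 + 0.12 * x1 + rnorm(n, sd = 0.08), 0), 1)
  d <- tibble::tibble(y = y, x1 = x1, as.data.frame(noise), w = rnorm(n))
  d$w[sample(n, 50)] <- NA
  imp <- mice_pmm(d, quickpred(d, forced = c("y", "x1")),
                  m = 5, maxit = 3, donors = 5, seed = 17)
  sel <- stepwise_backward_mi(imp, "y", c("x1", paste0("n", 1:4)),
                              alpha = 0.05)
  counts <- sel$counts
  expect_equal(counts$n_selected[counts$variable == "x1"], 5)
  expect_true("x1" %in% sel$selected)
  expect_true(all(counts$n_selected[counts$variable != "x1"] < 5))
  expect_true(all(counts$n_selected >= 0 & counts$n_selected <= 5))
  # retention rule: count >= ceiling(retain_frac * m)
  expect_equal(counts$retained, counts$n_selected >= ceiling(0.5 * 5))
  expect_s3_class(sel$pooled, "pooled_fit")
  expect_true("x1" %in% sel$pooled$table$term)

  # single strong candidate is retained in every dataset
  sel1 <- stepwise_backward_mi(imp, "y", "x1", alpha = 0.05)
  expect_equal(sel1$counts$n_selected, 5)

  # all-noise candidates at strict alpha: empty model is reported, not fatal
  sel0 <- stepwise_backward_mi(imp, "y", paste0("n", 1:4), alpha = 1e-6)
  expect_equal(sel0$selected, character(0))
  expect_null(sel0$pooled)
})
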