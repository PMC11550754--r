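# Correlation screening: the r/CI/p cell, the grid, and the exclusion rules.

test_that("pearson cell matches hand-computed and closed-form values", {
  cell <- pearson_with_ci(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(cell$r, 0.8)

  # perfect linearity
  x <- 1:10
  cell2 <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(cell2$r, 1)
  expect_lt(cell2$p_value, 1e-12)

  # Fisher-z closed form at r = 0, n = 403: tanh(qnorm(.975)/20)
  set.seed(1)
  x <- rnorm(403)
  y <- rnorm(403)
  y <- resid(lm(y ~ x))  # force exact sample orthogonality
  cell3 <- pearson_with_ci(x, y)
  expect_lt(abs(cell3$r), 1e-12)
  expect_equal(cell3$ci_high, tanh(qnorm(0.975) / sqrt(400)),
               tolerance = 1e-6)
  expect_equal(cell3$ci_high, 0.0976, tolerance = 1e-3)
  expect_equal(cell3$ci_low, -cell3$ci_high, tolerance = 1e-9)

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "length")
})

test_that("the correlation cell is symmetric in its arguments", {
  set.seed(2)
  x <- rnorm(50)
  y <- 0.4 * x + rnorm(50)
  a <- pearson_with_ci(x, y)
  b <- pearson_with_ci(y, x)
  expect_equal(a$r, b$r)
  expect_equal(a$p_value, b$p_value)
})

# Construct a cohort-like table with known structure: two informative
# inputs, one pure-noise input, one well-behaved output, one output that is
# negatively driven by the inputs.
screening_fixture <- function(n = 400, seed = 99) {
  withr::with_seed(seed, {
    in1 <- rnorm(n)
    in2 <- rnorm(n)
    noise <- rnorm(n)
    out_good <- 0.4 * in1 + 0.3 * in2 + rnorm(n)
    out_bad <- -0.35 * in1 - 0.3 * in2 + rnorm(n)
    data.frame(in1, in2, noise, out_good, out_bad)
  })
}

test_that("screening excludes noise inputs and wrong-sign outputs", {
  d <- screening_fixture()
  dec <- screen_variables(d, inputs = c("in1", "in2", "noise"),
                          outputs = c("out_good", "out_bad"))
  expect_setequal(dec$kept_inputs, c("in1", "in2"))
  expect_equal(dec$kept_outputs, "out_good")
  expect_equal(
    dec$excluded$reason[dec$excluded$variable == "noise"],
    "no-significant-correlation")
  expect_equal(
    dec$excluded$reason[dec$excluded$variable == "out_bad"],
    "wrong-sign")
  # the audit grid holds every candidate pair
  expect_equal(nrow(dec$grid), 6)
  # grid cells agree with the standalone oracle cell
  cell <- pearson_with_ci(d$in1, d$out_good)
  row <- dec$grid[dec$grid$input == "in1" & dec$grid$output == "out_good", ]
  expect_equal(row$r, cell$r)
  expect_equal(row$p_value, cell$p_value)
})

test_that("all-positive grids keep everything; empty candidates are rejected", {
  withr::with_seed(7, {
    f <- rnorm(300)
    d <- data.frame(a = f + rnorm(300, sd = 0.5),
                    b = f + rnorm(300, sd = 0.5),
                    u = f + rnorm(300, sd = 0.5),
                    v = f + rnorm(300, sd = 0.5))
  })
  dec <- screen_variables(d, c("a", "b"), c("u", "v"))
  expect_setequal(dec$kept_inputs, c("a", "b"))
  expect_setequal(dec$kept_outputs, c("u", "v"))
  expect_equal(nrow(dec$excluded), 0)

  expect_error(screen_variables(d, character(), c("u")), "nonempty")
})

test_that("the decision is invariant to row permutation", {
  d <- screening_fixture(n = 300, seed = 5)
  dec1 <- screen_variables(d, c("in1", "in2", "noise"),
                           c("out_good", "out_bad"))
  d2 <- d[sample(nrow(d)), ]
  dec2 <- screen_variables(d2, c("in1", "in2", "noise"),
                           c("out_good", "out_bad"))
  expect_identical(dec1$kept_inputs, dec2$kept_inputs)
  expect_identical(dec1$kept_outputs, dec2$kept_outputs)
  expect_equal(dec1$grid$r, dec2$grid$r)
})

test_that("rule variants behave as documented", {
  d <- screening_fixture()
  # "all" demands significance against every output; in1 correlates with
  # both outputs here, so it survives even the strict rule
  dec_all <- screen_variables(d, c("in1", "noise"), c("out_good", "out_bad"),
                              input_rule = "all")
  expect_false("noise" %in% dec_all$kept_inputs)
  # sign_rule = "any": a single significant negative kills the output
  withr::with_seed(13, {
    n <- 400
    i1 <- rnorm(n)
    i2 <- rnorm(n)
    mixed <- 0.4 * i1 - 0.25 * i2 + rnorm(n)
    dd <- data.frame(i1, i2, mixed)
  })
  lax <- screen_variables(dd, c("i1", "i2"), "mixed", sign_rule = "majority")
  strict <- screen_variables(dd, c("i1", "i2"), "mixed", sign_rule = "any")
  expect_equal(lax$kept_outputs, "mixed")
  expect_equal(strict$kept_outputs, character(0))
})
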