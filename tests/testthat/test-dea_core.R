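# BCC DEA core: hand-solved cases, LP-vs-grid oracle agreement, and the
# model's invariance properties.

test_that("hand-solved problems give exact expansions", {
  # single DMU evaluates itself
  s <- solve_output_bcc(matrix(2), matrix(3), 1)
  expect_equal(s$phi, 1)
  expect_equal(s$lambda, 1)
  expect_equal(s$score, 1)

  # same input, half the output: B can double within A's input
  s2 <- solve_output_bcc(matrix(c(1, 1), ncol = 1),
                         matrix(c(2, 1), ncol = 1), 2)
  expect_equal(s2$phi, 2)
  expect_equal(s2$score, 0.5)
  sA <- solve_output_bcc(matrix(c(1, 1), ncol = 1),
                         matrix(c(2, 1), ncol = 1), 1)
  expect_equal(sA$score, 1)

  # C projects onto the A-B frontier midpoint
  p <- abc_problem()
  s3 <- solve_output_bcc(p$X, p$Y, 3)
  expect_equal(s3$phi, 1.25)
  expect_equal(s3$score, 0.8)
  expect_equal(s3$lambda, c(0.5, 0.5, 0))
  expect_setequal(s3$peers, c(1, 2))
})

test_that("dea() solves every DMU and summarizes the frontier", {
  p <- abc_problem()
  d <- data.frame(x = p$X[, 1], y = p$Y[, 1])
  fit <- dea(d, "x", "y")
  td <- tidy(fit)
  expect_equal(td$score, c(1, 1, 0.8))
  g <- glance(fit)
  expect_equal(g$fraction_efficient, 2 / 3)
  expect_equal(g$n_efficient, 2L)

  # duplicated DMUs score identically
  d2 <- rbind(d, d[3, ])
  fit2 <- dea(d2, "x", "y")
  expect_equal(tidy(fit2)$score[3], tidy(fit2)$score[4])

  # any valid problem has a nonempty frontier
  set.seed(21)
  for (i in 1:5) {
    pr <- random_problem(7)
    f <- dea(data.frame(pr$X, pr$Y), names(data.frame(pr$X)),
             names(data.frame(pr$Y)))
    expect_gte(sum(tidy(f)$efficient), 1)
    expect_true(all(tidy(f)$score > 0 & tidy(f)$score <= 1 + 1e-9))
  }
})

test_that("grid oracle agrees with the LP on random small problems", {
  # the 3-DMU case at fine resolution
  p <- abc_problem()
  expect_lt(abs(brute_force_phi(p$X, p$Y, 3, resolution = 1e-3) - 1.25),
            2e-3)
  expect_equal(brute_force_phi(matrix(2), matrix(3), 1, resolution = 0.5), 1)

  set.seed(123)
  h <- 0.02
  for (i in 1:25) {
    pr <- random_problem(5)
    for (o in 1:5) {
      lp <- solve_output_bcc(pr$X, pr$Y, o)$phi
      grid <- brute_force_phi(pr$X, pr$Y, o, resolution = h)
      expect_lte(grid, lp + 1e-7)           # grid is a feasible lower bound
      expect_lte(lp - grid, 2 * h)
    }
  }

  expect_error(brute_force_phi(random_problem(7)$X, random_problem(7)$Y, 1),
               "6 DMUs")
  expect_error(brute_force_phi(matrix(2), matrix(3), 1, resolution = 0.7),
               "integer grid")
})

test_that("phi is invariant to units and to input translation", {
  set.seed(77)
  pr <- random_problem(8, 2, 2)
  phi0 <- vapply(1:8, function(o) solve_output_bcc(pr$X, pr$Y, o)$phi, 0)

  Xs <- pr$X
  Xs[, 1] <- Xs[, 1] * 7.3
  Ys <- pr$Y
  Ys[, 2] <- Ys[, 2] * 0.02
  phi_units <- vapply(1:8, function(o) solve_output_bcc(Xs, Ys, o)$phi, 0)
  expect_lt(max(abs(phi_units - phi0)), 1e-9)

  # adding a constant to an input column: the justification for the
  # pivot-subtraction inversion of alcohol and smoking
  Xt <- pr$X
  Xt[, 2] <- Xt[, 2] + 100
  phi_tr <- vapply(1:8, function(o) solve_output_bcc(Xt, pr$Y, o)$phi, 0)
  expect_lt(max(abs(phi_tr - phi0)), 1e-9)
})

test_that("dominated DMUs join without disturbing others; VRS >= CRS scores", {
  set.seed(42)
  pr <- random_problem(6, 2, 2)
  phi0 <- vapply(1:6, function(o) solve_output_bcc(pr$X, pr$Y, o)$phi, 0)
  # weakly dominated copy of DMU 1: more input, less output
  X2 <- rbind(pr$X, pr$X[1, ] * 1.3)
  Y2 <- rbind(pr$Y, pr$Y[1, ] * 0.7)
  phi1 <- vapply(1:6, function(o) solve_output_bcc(X2, Y2, o)$phi, 0)
  expect_lt(max(abs(phi1 - phi0)), 1e-9)

  for (o in 1:6) {
    svrs <- solve_output_bcc(pr$X, pr$Y, o, rts = "vrs")
    scrs <- solve_output_bcc(pr$X, pr$Y, o, rts = "crs")
    expect_gte(svrs$score, scrs$score - 1e-9)
    expect_gte(svrs$phi, 1)
    expect_equal(sum(svrs$lambda), 1, tolerance = 1e-7)
  }
})

test_that("invalid problems are rejected with diagnostics", {
  expect_error(solve_output_bcc(matrix(c(1, 0), ncol = 1),
                                matrix(c(1, 1), ncol = 1), 1),
               "strictly positive")
  expect_error(solve_output_bcc(matrix(c(1, NA), ncol = 1),
                                matrix(c(1, 1), ncol = 1), 1),
               "missing")
  expect_error(solve_output_bcc(matrix(1), matrix(1), 2), "dmu_index")
  expect_error(dea(data.frame(x = 1, y = 1), "x", "zz"), "not found")
})
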