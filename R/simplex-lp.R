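# Dense primal simplex for the DEA linear programs.
#
# Both DEA formulations used here reduce to
#     max c'z   s.t.  A z <= b,  z >= 0,  with b >= 0,
# so the slack basis is immediately feasible and no phase-1 is needed.
# Dantzig pricing with a switch to Bland's rule after a burn-in guarantees
# termination on the degenerate bases that DEA frontiers routinely produce
# (many DMUs tied on a facet).

simplex_max <- function(a, A, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (any(b < -tol)) abort("simplex_max requires b >= 0")
  max_iter <- max_iter %||% (50L * (m + n))
  # tableau: columns = structural vars, slacks, rhs; last row = reduced costs
  T <- cbind(A, diag(m), b)
  obj <- c(-a, rep(0, m + 1))
  basis <- n + seq_len(m)
  bland_after <- 10L * (m + n)
  for (iter in seq_len(max_iter)) {
    red <- obj[seq_len(n + m)]
    if (iter <= bland_after) {
      enter <- which.min(red)
      if (red[enter] >= -tol) break
    } else {
      neg <- which(red < -tol)
      if (!length(neg)) break
      enter <- neg[1L]                       # Bland: smallest index
    }
    col <- T[, enter]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", value = Inf, x = NULL))
    }
    ratios <- T[pos, n + m + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    # leaving tie-break on smallest basis index (with Bland this prevents
    # cycling; otherwise it is a reasonable lexicographic stand-in)
    leave <- cand[which.min(basis[cand])]
    piv <- T[leave, enter]
    T[leave, ] <- T[leave, ] / piv
    upd <- T[, enter]
    upd[leave] <- 0
    T <- T - outer(upd, T[leave, ])
    obj <- obj - obj[enter] * T[leave, ]
    basis[leave] <- enter
    if (iter == max_iter) {
      return(list(status = "iteration-limit", value = NA_real_, x = NULL))
    }
  }
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- T[inb, n + m + 1L]
  list(status = "optimal", value = sum(a * x), x = pmax(x, 0))
}

# Output-oriented DEA LP for one DMU. VRS eliminates the sum(lambda)=1
# equality by substituting lambda_o = 1 - sum_{j != o} lambda_j, which keeps
# every right-hand side non-negative:
#   inputs:  sum_{j!=o} lambda_j (x_ij - x_io)            <= 0
#   outputs: phi y_ro + sum_{j!=o} lambda_j (y_ro - y_rj) <= y_ro
#   mass:    sum_{j!=o} lambda_j                          <= 1
# CRS keeps all n lambdas with no mass constraint.
dea_lp <- function(X, Y, o, rts = "vrs", tol = 1e-9) {
  n <- nrow(X)
  if (rts == "vrs") {
    others <- setdiff(seq_len(n), o)
    Xd <- X[others, , drop = FALSE] -
      matrix(X[o, ], length(others), ncol(X), byrow = TRUE)
    Yd <- matrix(Y[o, ], length(others), ncol(Y), byrow = TRUE) -
      Y[others, , drop = FALSE]
    A <- rbind(cbind(0, t(Xd)),
               cbind(Y[o, ], t(Yd)),
               c(0, rep(1, length(others))))
    b <- c(rep(0, ncol(X)), Y[o, ], 1)
    a <- c(1, rep(0, length(others)))
    sol <- simplex_max(a, A, b, tol = tol)
    if (sol$status != "optimal") return(sol)
    lambda <- numeric(n)
    lambda[others] <- sol$x[-1]
    lambda[o] <- max(0, 1 - sum(sol$x[-1]))
    list(status = "optimal", phi = sol$x[1], lambda = lambda)
  } else {
    A <- rbind(cbind(0, t(X)),
               cbind(Y[o, ], -t(Y)))
    b <- c(X[o, ], rep(0, ncol(Y)))
    a <- c(1, rep(0, n))
    sol <- simplex_max(a, A, b, tol = tol)
    if (sol$status != "optimal") return(sol)
    list(status = "optimal", phi = sol$x[1], lambda = sol$x[-1])
  }
}
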