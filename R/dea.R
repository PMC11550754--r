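# Output-oriented BCC (variable returns-to-scale) data envelopment analysis.
#
# For DMU o the LP is
#   max phi  s.t.  sum_j lambda_j x_ij <= x_io          (each input i)
#                  sum_j lambda_j y_rj >= phi y_ro       (each output r)
#                  sum_j lambda_j = 1                    (VRS only)
#                  lambda >= 0
# phi >= 1 is the Farrell output expansion ("inefficiency score"); the
# efficiency score is 1/phi in (0, 1].

validate_dea_matrices <- function(X, Y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have one row per DMU")
  if (nrow(X) < 1) abort("at least one DMU is required")
  if (anyNA(X) || anyNA(Y)) abort("DEA matrices must have no missing cells")
  if (any(X <= 0) || any(Y <= 0)) {
    abort("all DEA inputs and outputs must be strictly positive; run make_positive()/invert_detrimental() first")
  }
  list(X = X, Y = Y)
}

#' Solve the output-oriented BCC model for one DMU
#'
#' Linear program solved by a dense primal simplex with Bland anti-cycling
#' (DEA frontiers routinely produce degenerate bases, which trip generic
#' textbook implementations). Under variable returns to scale the optimum
#' always exists for valid positive data (the DMU's own point is feasible
#' with phi = 1), so a solver failure is surfaced as an error — it signals
#' corrupted data, not a modelling condition.
#'
#' @param X,Y strictly positive input (n x m) and output (n x s) matrices,
#'   one row per DMU.
#' @param dmu_index row index of the DMU under evaluation.
#' @param rts returns to scale: `"vrs"` (BCC, sum(lambda) = 1) or `"crs"`.
#' @param lambda_tol peers are DMUs with lambda above this tolerance.
#' @return A list: `phi` (>= 1), `score` (= 1/phi), `lambda` (length-n
#'   weight vector), `peers` (integer indices), `status` ("optimal").
#' @export
#' @examples
#' X <- matrix(c(1, 3, 2), ncol = 1)
#' Y <- matrix(c(1, 4, 2), ncol = 1)
#' solve_output_bcc(X, Y, 3)$phi  # 1.25 on the A-B frontier segment
solve_output_bcc <- function(X, Y, dmu_index, rts = c("vrs", "crs"),
                             lambda_tol = 1e-6) {
  rts <- match.arg(rts)
  m <- validate_dea_matrices(X, Y)
  X <- m$X; Y <- m$Y
  n <- nrow(X)
  if (!is_number(dmu_index) || dmu_index < 1 || dmu_index > n) {
    abort(sprintf("`dmu_index` must be in [1, %d]", n))
  }
  o <- as.integer(dmu_index)
  sol <- dea_lp(X, Y, o, rts = rts)
  if (sol$status != "optimal") {
    abort(sprintf(
      "LP for DMU %d did not reach a finite optimum (status '%s'); inputs/outputs are likely corrupted (non-positive or non-finite values)",
      o, sol$status))
  }
  phi <- sol$phi
  lambda <- sol$lambda
  # post-checks at a small feasibility slack
  slack <- 1e-9 * max(1, max(abs(X)), max(abs(Y)))
  if (phi < 1 - 1e-6) {
    abort(sprintf("DMU %d returned phi = %.8f < 1; solver output inconsistent", o, phi))
  }
  if (rts == "vrs" && abs(sum(lambda) - 1) > 1e-7) {
    abort(sprintf("DMU %d: lambda weights sum to %.8f, not 1", o, sum(lambda)))
  }
  if (any(as.numeric(t(X) %*% lambda) > X[o, ] + slack + 1e-7 * max(X))) {
    warn(sprintf("DMU %d: input constraint violated beyond tolerance", o))
  }
  phi <- max(phi, 1)
  list(dmu = o, phi = phi, score = 1 / phi, lambda = lambda,
       peers = which(lambda > lambda_tol), status = "optimal")
}

#' Data envelopment analysis of a cohort table
#'
#' Runs the output-oriented BCC model for every DMU (participant) and
#' collects Farrell expansion factors, efficiency scores, lambda weights and
#' peer sets.
#'
#' @param data data frame with one row per DMU.
#' @param inputs,outputs column names of the (strictly positive) DEA inputs
#'   and outputs.
#' @param id_col optional column with DMU identifiers; row numbers are used
#'   otherwise.
#' @param rts `"vrs"` (default) or `"crs"`.
#' @param lambda_tol peer-membership tolerance on lambda.
#' @return An object of class `"dea_fit"`; use [tidy()] for the per-DMU
#'   tibble (`dmu`, `phi`, `score`, `efficient`, `n_peers`), [glance()] for
#'   the one-row summary (mean score, fraction efficient), and [autoplot()]
#'   for the score distribution.
#' @export
#' @examples
#' d <- data.frame(x = c(1, 3, 2), y = c(1, 4, 2))
#' fit <- dea(d, inputs = "x", outputs = "y")
#' tidy(fit)
#' glance(fit)
dea <- function(data, inputs, outputs, id_col = NULL,
                rts = c("vrs", "crs"), lambda_tol = 1e-6) {
  stop_if_not_df(data)
  rts <- match.arg(rts)
  check_cols(data, c(inputs, outputs, id_col))
  X <- as.matrix(data[, inputs, drop = FALSE])
  Y <- as.matrix(data[, outputs, drop = FALSE])
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  validate_dea_matrices(X, Y)
  n <- nrow(X)
  ids <- if (is.null(id_col)) seq_len(n) else data[[id_col]]
  sols <- lapply(seq_len(n), function(o) {
    tryCatch(solve_output_bcc(X, Y, o, rts = rts, lambda_tol = lambda_tol),
             error = function(e) {
               abort(sprintf("DEA failed at DMU %s: %s", ids[o],
                             conditionMessage(e)))
             })
  })
  lambda <- do.call(rbind, lapply(sols, `[[`, "lambda"))
  results <- tibble(
    dmu = ids,
    phi = vapply(sols, `[[`, 0, "phi"),
    score = vapply(sols, `[[`, 0, "score"),
    status = vapply(sols, `[[`, "", "status"))
  results$efficient <- results$score >= 1 - 1e-7
  results$peers <- lapply(sols, `[[`, "peers")
  results$n_peers <- lengths(results$peers)
  structure(
    list(results = results, lambda = lambda, X = X, Y = Y,
         inputs = inputs, outputs = outputs, ids = ids,
         rts = rts, lambda_tol = lambda_tol),
    class = "dea_fit")
}

#' @export
print.dea_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dea_fit> %s, output-oriented: %d DMUs, %d inputs, %d outputs\n",
              toupper(x$rts), g$n_dmu, length(x$inputs), length(x$outputs)))
  cat(sprintf("  mean score %.3f; %d/%d efficient (%.1f%%)\n",
              g$mean_score, g$n_efficient, g$n_dmu,
              100 * g$fraction_efficient))
  invisible(x)
}

#' @export
tidy.dea_fit <- function(x, ...) {
  dplyr::select(x$results, "dmu", "phi", "score", "efficient", "n_peers",
                "status")
}

#' @export
glance.dea_fit <- function(x, ...) {
  s <- x$results$score
  tibble(n_dmu = length(s),
         mean_score = mean(s),
         sd_score = sd(s),
         min_score = min(s),
         n_efficient = sum(x$results$efficient),
         fraction_efficient = mean(x$results$efficient),
         rts = x$rts)
}

#' @export
autoplot.dea_fit <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white", boundary = 1) +
    ggplot2::geom_vline(xintercept = mean(df$score), linetype = 2) +
    ggplot2::labs(x = "Efficiency score (1/phi)", y = "Participants",
                  title = sprintf("Efficiency scores (%s, output-oriented)",
                                  toupper(object$rts))) +
    ggplot2::theme_minimal()
}

#' Grid-search oracle for the output expansion factor
#'
#' Independent check of the LP: enumerates lambda on a regular simplex grid
#' of step `resolution`, keeps the input-feasible points, and for each
#' computes the largest feasible expansion phi(lambda) = min_r
#' (lambda'Y)_r / y_ro; the maximum over the grid is a lower bound on the LP
#' optimum that converges at rate O(resolution). Intended for small problems
#' (n <= 6 DMUs).
#'
#' @param X,Y strictly positive DEA matrices.
#' @param dmu_index DMU under evaluation.
#' @param resolution simplex grid step (1/resolution must be an integer).
#' @param rts only `"vrs"` grids are supported.
#' @param refine run a second, local grid pass at a quarter of the step
#'   around the coarse optimum (cuts the discretization constant without
#'   enumerating the fine grid globally).
#' @return The best feasible phi found on the grid.
#' @export
brute_force_phi <- function(X, Y, dmu_index, resolution = 0.01,
                            rts = "vrs", refine = TRUE) {
  if (!identical(rts, "vrs")) abort("the grid oracle only supports VRS")
  m <- validate_dea_matrices(X, Y)
  X <- m$X; Y <- m$Y
  n <- nrow(X)
  if (n > 6) abort("the grid oracle is limited to 6 DMUs")
  k <- round(1 / resolution)
  if (abs(k - 1 / resolution) > 1e-8) {
    abort("1/resolution must be an integer grid count")
  }
  if (k < 2) abort("grid too coarse: use a resolution of 0.5 or finer")
  o <- as.integer(dmu_index)
  best <- grid_best_phi(compositions(k, n) / k, X, Y, o)
  if (is.null(best)) abort("no feasible grid point; grid too coarse")
  phi <- best$phi
  if (refine && n >= 2) {
    fac <- 4L
    span <- 2L * fac                      # +-2 coarse steps, at step/fac
    k2 <- k * fac
    centre <- round(best$lambda * k2)
    G <- offset_grid(n - 1L, span)
    Mfull <- sweep(G, 2, centre[-n], "+")
    lastc <- k2 - rowSums(Mfull)
    keep <- lastc >= 0 & abs(lastc - centre[n]) <= span &
      rowSums(Mfull < 0) == 0
    if (any(keep)) {
      L2 <- cbind(Mfull[keep, , drop = FALSE], lastc[keep]) / k2
      fine <- grid_best_phi(L2, X, Y, o)
      if (!is.null(fine)) phi <- max(phi, fine$phi)
    }
  }
  phi
}

# Best feasible expansion over a fixed set of lambda rows.
grid_best_phi <- function(L, X, Y, o) {
  feas <- rep(TRUE, nrow(L))
  LX <- L %*% X
  for (i in seq_len(ncol(X))) feas <- feas & (LX[, i] <= X[o, i] + 1e-12)
  if (!any(feas)) return(NULL)
  L <- L[feas, , drop = FALSE]
  LY <- L %*% Y
  phis <- LY[, 1] / Y[o, 1]
  for (r in seq_len(ncol(Y))[-1]) phis <- pmin(phis, LY[, r] / Y[o, r])
  i <- which.max(phis)
  list(phi = phis[i], lambda = L[i, ])
}
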