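# Peer-based lack-of-output decomposition: for an inefficient DMU, each
# output's personalized target is the lambda-weighted composite of its
# frontier peers; the "lack" is composite minus the DMU's own value.

#' Per-peer lambda-weighted outputs
#'
#' For each peer j and output r the weighted value is lambda_j * y_rj; the
#' peers' weighted rows sum to the composite (virtual) output that the
#' evaluated DMU is compared against.
#'
#' @param lambda non-negative weight vector over DMUs (one optimal solution
#'   of the BCC program).
#' @param Y output matrix (n_dmu x n_out) or data frame.
#' @param rts returns-to-scale of the solution; under `"vrs"` the weights
#'   must sum to 1 within `sum_tol`.
#' @param sum_tol tolerance on `sum(lambda) - 1`. The default is strict;
#'   loosen it only for weights quoted at low precision (e.g. values
#'   re-typed from a published table).
#' @param lambda_tol peers are entries with lambda above this tolerance.
#' @return A tibble: `peer` (row index), `lambda`, one column per output
#'   with the weighted values.
#' @export
weighted_peer_outputs <- function(lambda, Y, rts = "vrs", sum_tol = 1e-6,
                                  lambda_tol = 1e-6) {
  Y <- as.matrix(Y)
  if (length(lambda) != nrow(Y)) {
    abort("`lambda` must have one weight per row of `Y`")
  }
  if (any(lambda < -1e-12)) abort("lambda weights must be non-negative")
  if (identical(rts, "vrs") && abs(sum(lambda) - 1) > sum_tol) {
    abort(sprintf(
      "lambda weights sum to %.6f; a VRS solution must sum to 1 (tolerance %g)",
      sum(lambda), sum_tol))
  }
  peers <- which(lambda > lambda_tol)
  W <- Y[peers, , drop = FALSE] * lambda[peers]
  out <- tibble(peer = peers, lambda = lambda[peers])
  dplyr::bind_cols(out, as_tibble(as.data.frame(W)))
}

#' Composite (virtual) outputs of the peer set
#'
#' Column-wise sum of the lambda-weighted peer outputs: the output bundle of
#' the convex peer combination the DMU is projected onto.
#'
#' @param weighted tibble from [weighted_peer_outputs()], or any data frame
#'   whose non-`peer`/`lambda` columns are weighted outputs.
#' @return A named numeric vector, one composite per output.
#' @export
composite_outputs <- function(weighted) {
  stop_if_not_df(weighted, "weighted")
  cols <- setdiff(names(weighted), c("peer", "lambda"))
  if (!length(cols)) abort("no output columns found")
  vapply(weighted[cols], sum, numeric(1))
}

#' Lack of output
#'
#' Element-wise difference between the peer composite and the DMU's own
#' outputs: how much of each output the DMU would need to gain to reach its
#' projection on the frontier. Negative lacks beyond tolerance signal a
#' mismatch between the lambda solution and the output matrix and are
#' flagged with a warning.
#'
#' @param composite named vector from [composite_outputs()].
#' @param own_outputs the DMU's own output values, same length/order.
#' @param tol flag threshold for negative lacks.
#' @return Numeric vector of lacks (composite - own).
#' @export
lack_of_output <- function(composite, own_outputs, tol = 1e-7) {
  if (length(composite) != length(own_outputs)) {
    abort("`composite` and `own_outputs` must align")
  }
  lack <- composite - as.numeric(own_outputs)
  if (any(lack < -tol)) {
    warn(sprintf(
      "negative lack of output (min %.3g): lambda weights and Y are inconsistent",
      min(lack)))
  }
  lack
}

#' Personalized lack-of-output report for one DMU
#'
#' Assembles the full peer decomposition for one evaluated participant: each
#' peer's lambda, raw and weighted outputs, the composite row, the DMU's own
#' outputs, the lack of output, and — when transform records are supplied —
#' the lack re-expressed on the original measurement scale (permille
#' abundance, diversity units) by back-transforming own + lack and own and
#' differencing.
#'
#' @param fit a [dea()] fit.
#' @param dmu DMU identifier (matching `fit$ids`) or row index.
#' @param transforms optional transforms tibble from [prepare_dea_inputs()]
#'   / [make_positive()]; without it the report omits the back-transformed
#'   row (with a warning) since the DEA scale is then the only known scale.
#' @return An object of class `"lack_report"`; `tidy()` returns the per-peer
#'   table, `print()` renders the fixed-width layout with weighted values,
#'   composite sums and the lack row.
#' @export
lack_report <- function(fit, dmu, transforms = NULL) {
  if (!inherits(fit, "dea_fit")) abort("`fit` must be a dea_fit")
  idx <- if (dmu %in% fit$ids) which(fit$ids == dmu)[1] else as.integer(dmu)
  if (is.na(idx) || idx < 1 || idx > nrow(fit$Y)) {
    abort(sprintf("DMU '%s' not found", dmu))
  }
  lambda <- fit$lambda[idx, ]
  weighted <- weighted_peer_outputs(lambda, fit$Y, rts = fit$rts,
                                    lambda_tol = fit$lambda_tol)
  composite <- composite_outputs(weighted)
  own <- fit$Y[idx, ]
  lack <- lack_of_output(composite, own)
  efficient <- fit$results$efficient[idx]
  if (efficient) lack[abs(lack) <= 1e-7] <- 0

  back <- NULL
  if (!is.null(transforms)) {
    missing_rec <- setdiff(fit$outputs, transforms$variable)
    if (length(missing_rec)) {
      warn(sprintf(
        "no transform record for output(s) %s; back-transformed row omitted",
        paste(missing_rec, collapse = ", ")))
    } else {
      back <- vapply(seq_along(fit$outputs), function(r) {
        v <- fit$outputs[r]
        back_transform(own[r] + lack[r], transforms, v) -
          back_transform(own[r], transforms, v)
      }, numeric(1))
      names(back) <- fit$outputs
    }
  } else {
    warn("no transform records supplied; back-transformed row omitted")
  }
  peer_raw <- fit$Y[weighted$peer, , drop = FALSE]
  structure(
    list(dmu = fit$ids[idx], efficient = efficient,
         score = fit$results$score[idx], phi = fit$results$phi[idx],
         outputs = fit$outputs,
         peers = tibble(peer = fit$ids[weighted$peer],
                        lambda = weighted$lambda),
         peer_raw = peer_raw,
         weighted = weighted,
         composite = composite, own = setNames(as.numeric(own), fit$outputs),
         lack = setNames(lack, fit$outputs),
         back_transformed = back),
    class = "lack_report")
}

#' @export
tidy.lack_report <- function(x, ...) {
  w <- x$weighted
  w$peer <- x$peers$peer
  w
}

#' @export
print.lack_report <- function(x, digits = 3, ...) {
  wfmt <- function(v) formatC(v, digits = digits, format = "f", width = 10)
  cat(sprintf("Lack-of-output report for DMU %s (score %.3f%s)\n",
              x$dmu, x$score, if (x$efficient) ", efficient" else ""))
  cat(sprintf("%-22s%s\n", "", paste(formatC(x$outputs, width = 10),
                                     collapse = "")))
  for (i in seq_len(nrow(x$peers))) {
    cat(sprintf("Peer %-17s%s\n",
                sprintf("%s (l=%.3f)", x$peers$peer[i], x$peers$lambda[i]),
                paste(wfmt(x$peer_raw[i, ]), collapse = "")))
    cat(sprintf("  %-20s%s\n", "weighted value",
                paste(wfmt(as.numeric(x$weighted[i, x$outputs])),
                      collapse = "")))
  }
  cat(sprintf("%-22s%s\n", "Sum of weighted values",
              paste(wfmt(x$composite), collapse = "")))
  cat(sprintf("%-22s%s\n", "Own value",
              paste(wfmt(x$own), collapse = "")))
  cat(sprintf("%-22s%s\n", "Lack of output",
              paste(wfmt(x$lack), collapse = "")))
  if (!is.null(x$back_transformed)) {
    cat(sprintf("%-22s%s\n", "Back-transformed lack",
                paste(wfmt(x$back_transformed), collapse = "")))
  }
  invisible(x)
}

#' @export
autoplot.lack_report <- function(object, ...) {
  df <- tibble(output = factor(object$outputs, levels = object$outputs),
               own = object$own, composite = object$composite,
               lack = object$lack)
  long <- tidyr::pivot_longer(df, c("own", "composite"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$output, y = .data$value,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Output (DEA scale)",
                  title = sprintf("Peer composite vs own outputs, DMU %s",
                                  object$dmu),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
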