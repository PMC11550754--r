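# Correlation-based variable screening for the DEA model: every candidate
# input is correlated with every candidate output; variables without a
# significant (correctly signed) association are dropped before the frontier
# is built.

#' Pearson correlation with confidence interval and p-value
#'
#' Product-moment correlation with the two-sided p-value from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom and a Fisher-z
#' confidence interval (z +- z_{1-alpha/2}/sqrt(n-3), back-transformed).
#'
#' @param x,y numeric vectors of equal length (n >= 4), neither constant.
#' @param alpha significance level; the CI has level `1 - alpha`.
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_with_ci(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
pearson_with_ci <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n || n < 4) {
    abort("`x` and `y` must have equal length >= 4")
  }
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a constant column")
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = 1 - alpha)
  tibble(r = unname(ct$estimate),
         ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
         p_value = ct$p.value, n = n)
}

#' Screen DEA candidate variables by input-output correlation
#'
#' Computes the full Pearson grid between candidate inputs and outputs, then
#' applies the exclusion rules: an input is dropped when it shows no
#' significant correlation with any output (`input_rule = "any"`; the
#' stricter `"all"` keeps an input only when every output correlation is
#' significant); an output is dropped when it has no significant input
#' correlation, or when its significant correlations are negative — a
#' beneficial microbiota output should respond *positively* to beneficial
#' (or inverted-detrimental) inputs, so a negative association signals the
#' variable does not fit the model (`sign_rule = "majority"` drops when more
#' than half the significant correlations are negative; `"any"` drops on a
#' single significant negative).
#'
#' @param data data frame holding all candidate columns (DEA-ready scale:
#'   detrimental inputs already inverted).
#' @param inputs,outputs character vectors of candidate column names.
#' @param alpha significance level for the exclusion rules.
#' @param input_rule,sign_rule rule variants, see Details.
#' @return An object of class `"screening_decision"`: a list with
#'   `kept_inputs`, `kept_outputs`, `excluded` (tibble: variable, role,
#'   reason) and `grid` (the full correlation audit trail).
#' @export
screen_variables <- function(data, inputs, outputs, alpha = 0.05,
                             input_rule = c("any", "all"),
                             sign_rule = c("majority", "any")) {
  stop_if_not_df(data)
  input_rule <- match.arg(input_rule)
  sign_rule <- match.arg(sign_rule)
  if (!length(inputs) || !length(outputs)) {
    abort("candidate input and output sets must be nonempty")
  }
  check_cols(data, c(inputs, outputs))
  grid <- tidyr::expand_grid(input = inputs, output = outputs)
  cells <- purrr::pmap(grid, function(input, output) {
    pearson_with_ci(data[[input]], data[[output]], alpha)
  })
  grid <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))

  sig <- grid$p_value <= alpha
  keep_in <- vapply(inputs, function(v) {
    s <- sig[grid$input == v]
    if (input_rule == "any") any(s) else all(s)
  }, TRUE)
  excl <- list()
  for (v in inputs[!keep_in]) {
    excl[[length(excl) + 1]] <- tibble(variable = v, role = "input",
                                       reason = "no-significant-correlation")
  }
  keep_out <- logical(length(outputs))
  names(keep_out) <- outputs
  for (v in outputs) {
    rows <- grid$output == v & grid$input %in% inputs[keep_in]
    s <- grid$p_value[rows] <= alpha
    if (!any(s)) {
      keep_out[v] <- FALSE
      excl[[length(excl) + 1]] <- tibble(variable = v, role = "output",
                                         reason = "no-significant-correlation")
      next
    }
    neg <- grid$r[rows][s] < 0
    wrong <- if (sign_rule == "majority") mean(neg) > 0.5 else any(neg)
    if (wrong) {
      keep_out[v] <- FALSE
      excl[[length(excl) + 1]] <- tibble(variable = v, role = "output",
                                         reason = "wrong-sign")
    } else {
      keep_out[v] <- TRUE
    }
  }
  structure(
    list(kept_inputs = inputs[keep_in],
         kept_outputs = outputs[keep_out],
         excluded = dplyr::bind_rows(excl),
         grid = grid,
         alpha = alpha, input_rule = input_rule, sign_rule = sign_rule),
    class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat("<screening_decision> alpha =", x$alpha, "\n")
  cat("  kept inputs: ", paste(x$kept_inputs, collapse = ", "), "\n")
  cat("  kept outputs:", paste(x$kept_outputs, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("  excluded:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat("   -", x$excluded$variable[i],
          paste0("(", x$excluded$role[i], "): "), x$excluded$reason[i], "\n")
    }
  }
  invisible(x)
}

#' @export
tidy.screening_decision <- function(x, ...) x$grid
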