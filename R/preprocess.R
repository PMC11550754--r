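# Preprocessing: unit conversions, energy-residual adjustment, inversion of
# detrimental inputs, sleep imputation, and strictly-positive transforms with
# invertible records.

#' Unit conversions for intake variables
#'
#' `sodium_to_salt()` converts sodium intake (g/d) to salt-equivalent intake
#' (g/d) by the factor 2.54; `grams_to_alcohol_units()` converts grams of
#' ethanol per day into standard units of 21 g.
#'
#' @param sodium_g_per_day,grams_per_day non-negative numeric vectors.
#' @return A numeric vector of the same length.
#' @export
#' @examples
#' sodium_to_salt(1.0)       # 2.54
#' grams_to_alcohol_units(21) # 1
sodium_to_salt <- function(sodium_g_per_day) {
  if (any(sodium_g_per_day < 0, na.rm = TRUE)) {
    abort("sodium intake must be non-negative")
  }
  2.54 * sodium_g_per_day
}

#' @rdname sodium_to_salt
#' @export
grams_to_alcohol_units <- function(grams_per_day) {
  if (any(grams_per_day < 0, na.rm = TRUE)) {
    abort("alcohol grams must be non-negative")
  }
  grams_per_day / 21
}

#' Energy adjustment by the residual method
#'
#' Regresses a nutrient intake on total energy intake by ordinary least
#' squares and returns the residual plus the predicted intake at the sample
#' mean energy. The adjusted column is uncorrelated with energy and keeps the
#' original mean, so it isolates nutrient *composition* from eating volume.
#'
#' @param nutrient_column,energy_column numeric vectors of equal length
#'   (at least 3, no missing values); energy must not be constant.
#' @return The adjusted nutrient vector.
#' @export
#' @examples
#' energy_adjust_residual(c(10, 20, 30), c(1000, 1500, 2000)) # all 20
energy_adjust_residual <- function(nutrient_column, energy_column) {
  n <- length(nutrient_column)
  if (length(energy_column) != n || n < 3) {
    abort("nutrient and energy columns must have equal length >= 3")
  }
  if (anyNA(nutrient_column) || anyNA(energy_column)) {
    abort("energy adjustment requires complete columns")
  }
  if (var(energy_column) <= 0) {
    abort("energy intake is constant; the residual-method regression is undefined")
  }
  fit <- lm(nutrient_column ~ energy_column)
  # residual + fit at mean energy; the OLS line passes through the means, so
  # the second term is mean(nutrient)
  as.numeric(resid(fit)) + mean(nutrient_column)
}

#' Invert a detrimental input
#'
#' DEA requires that more of every input be "worse" for efficiency; for
#' consumption variables that harm the microbiota (alcohol, smoking) the
#' scale is reversed by subtracting from a pivot above the observed maximum,
#' so that heavier consumption becomes a smaller DEA input. Output-oriented
#' efficiency under variable returns to scale is invariant to this input
#' translation, which is what licenses the preprocessing.
#'
#' @param value non-negative numeric vector, strictly below `pivot`.
#' @param pivot positive scalar; defaults used in the pipeline are 5.5
#'   (alcohol units/d) and 90 (cigarettes/d).
#' @return `pivot - value`.
#' @export
#' @examples
#' invert_detrimental(0, 5.5)   # abstinent drinker -> 5.5
#' invert_detrimental(20, 90)   # 20 cigarettes/d -> 70
invert_detrimental <- function(value, pivot) {
  stopifnot(is_number(pivot), pivot > 0)
  if (any(value < 0, na.rm = TRUE)) {
    abort("values must be non-negative")
  }
  if (any(value >= pivot, na.rm = TRUE)) {
    abort(sprintf(
      "value(s) at or above the pivot %g; raise the pivot so all inverted inputs stay strictly positive", pivot))
  }
  pivot - value
}

#' Impute missing sleep time with a fixed value
#'
#' Missing self-reported sleep entries are replaced by 6.5 h/d (the cohort's
#' mean and median); observed entries are untouched.
#'
#' @param column numeric vector of sleep hours, possibly with `NA`s.
#' @param value replacement value in hours.
#' @return The completed vector.
#' @export
impute_sleep <- function(column, value = 6.5) {
  column[is.na(column)] <- value
  column
}

# Single-column positivity transform. Returns the shifted column and a
# one-row transform record. delta rule: (min positive gap)/2 - min(x); for a
# column whose minimum is 0 this is half the smallest positive value.
shift_positive <- function(x, variable = "x") {
  if (anyNA(x)) abort(sprintf("'%s' has missing values", variable))
  m <- min(x)
  if (m > 0) {
    return(list(x = x,
                record = tibble(variable = variable, kind = "identity",
                                pivot = NA_real_, delta = NA_real_)))
  }
  pos <- x[x > m]
  if (!length(pos)) {
    abort(sprintf("'%s' is constant at %g and cannot be made positive",
                  variable, m))
  }
  delta <- (min(pos) - m) / 2 - m
  list(x = x + delta,
       record = tibble(variable = variable, kind = "shift",
                       pivot = NA_real_, delta = delta))
}

#' Make DEA columns strictly positive with invertible records
#'
#' The DEA model requires strictly positive inputs and outputs; genus
#' relative abundances contain structural zeros. Each column with
#' non-positive values is shifted by a recorded constant delta equal to half
#' the smallest positive value when the minimum is 0 (zeros map to delta),
#' generalized so that a negative minimum (possible after energy-residual
#' adjustment) lands at half the smallest positive gap. Strictly positive
#' columns get an identity record. The shift is strictly monotone, so
#' within-column rankings are preserved, and every record is sufficient to
#' back-transform exactly.
#'
#' @param data data frame.
#' @param cols character vector of columns to transform (default: all
#'   numeric columns).
#' @param allow_negative if `FALSE` (default) columns with negative values
#'   are rejected: negativity is expected only from the energy-adjustment
#'   path, which opts in.
#' @return A list with `data` (tibble with transformed columns) and
#'   `transforms` (tibble: `variable`, `kind`, `pivot`, `delta`).
#' @seealso [back_transform()]
#' @export
#' @examples
#' mp <- make_positive(data.frame(ab = c(0, 0.06, 0.5)), "ab")
#' mp$data$ab        # 0.03 0.09 0.53: zeros become delta = 0.06/2
#' mp$transforms
make_positive <- function(data, cols = NULL,
                          allow_negative = FALSE) {
  stop_if_not_df(data)
  cols <- cols %||% names(data)[vapply(data, is.numeric, TRUE)]
  check_cols(data, cols)
  out <- as_tibble(data)
  records <- vector("list", length(cols))
  for (i in seq_along(cols)) {
    v <- cols[i]
    if (!allow_negative && any(out[[v]] < 0)) {
      abort(sprintf(
        "'%s' has negative values; detrimental variables must be inverted before make_positive()", v))
    }
    sp <- shift_positive(out[[v]], v)
    out[[v]] <- sp$x
    records[[i]] <- sp$record
  }
  list(data = out, transforms = dplyr::bind_rows(records))
}

#' Back-transform DEA-scale values to the original scale
#'
#' Inverts the recorded preprocessing transform for one variable: a shift is
#' subtracted, an inversion is reflected about its pivot, identity is
#' returned unchanged.
#'
#' @param values numeric vector on the transformed (DEA) scale.
#' @param record one row of a transforms tibble, or a transforms tibble plus
#'   `variable` to select the row.
#' @param variable variable name when `record` has several rows.
#' @return Values on the original measurement scale.
#' @export
back_transform <- function(values, record, variable = NULL) {
  stop_if_not_df(record)
  if (nrow(record) != 1) {
    if (is.null(variable)) {
      abort("`record` has several rows; supply `variable`")
    }
    record <- record[record$variable == variable, ]
    if (nrow(record) != 1) {
      abort(sprintf("no transform record for '%s'", variable))
    }
  }
  switch(record$kind,
    identity = values,
    shift = values - record$delta,
    inversion = record$pivot - values,
    abort(sprintf("unknown transform kind '%s'", record$kind))
  )
}

#' Build the DEA-ready table from a cohort
#'
#' Applies the full preprocessing chain: sleep imputation (6.5 h), residual
#' energy adjustment of nutrient intakes, inversion of detrimental inputs
#' (alcohol, cigarettes) about their pivots, and the recorded positivity
#' shift on every candidate column. Returns the transformed candidate
#' columns together with the transform records needed to express
#' lack-of-output recommendations on the original scale.
#'
#' @param cohort cohort tibble (e.g. [generate_cohort()]).
#' @param inputs,outputs candidate DEA input/output columns.
#' @param pivots named vector of inversion pivots for detrimental inputs.
#' @param energy_adjust apply the residual method to nutrient inputs?
#' @param energy_col column holding total energy intake.
#' @param adjust_cols nutrient columns to energy-adjust (intersection with
#'   `inputs` is used).
#' @param sleep_value replacement for missing sleep entries.
#' @return A list with `data` (tibble: id + transformed columns), `inputs`,
#'   `outputs`, and `transforms` (one record per DEA column).
#' @export
prepare_dea_inputs <- function(cohort,
                               inputs = dea_input_candidates(),
                               outputs = dea_output_candidates(),
                               pivots = c(alcohol_units = 5.5,
                                          cigarettes_day = 90),
                               energy_adjust = TRUE,
                               energy_col = "energy_kcal",
                               adjust_cols = c("mufa_g", "n3pufa_g",
                                               "n6pufa_g", "fiber_sol_g",
                                               "fiber_insol_g"),
                               sleep_value = 6.5) {
  stop_if_not_df(cohort, "cohort")
  check_cols(cohort, c(inputs, outputs), "cohort")
  out <- as_tibble(cohort)
  if ("sleep_h" %in% inputs) {
    out$sleep_h <- impute_sleep(out$sleep_h, sleep_value)
  }
  if (energy_adjust) {
    check_cols(cohort, energy_col, "cohort")
    for (v in intersect(adjust_cols, inputs)) {
      out[[v]] <- energy_adjust_residual(out[[v]], out[[energy_col]])
    }
  }
  records <- list()
  for (v in intersect(names(pivots), inputs)) {
    out[[v]] <- invert_detrimental(out[[v]], pivots[[v]])
    records[[v]] <- tibble(variable = v, kind = "inversion",
                           pivot = pivots[[v]], delta = NA_real_)
  }
  rest <- setdiff(c(inputs, outputs), names(records))
  mp <- make_positive(out[, rest, drop = FALSE], rest, allow_negative = TRUE)
  out[rest] <- mp$data
  transforms <- dplyr::bind_rows(dplyr::bind_rows(records), mp$transforms)
  id <- intersect("participant_id", names(out))
  list(data = out[, c(id, inputs, outputs)],
       inputs = inputs, outputs = outputs,
       transforms = transforms)
}
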