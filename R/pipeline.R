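# End-to-end orchestration: cohort (synthetic or loaded) -> preprocessing ->
# screening -> DEA -> lack-of-output reports -> Tobit/MI regression, with
# file artifacts per stage so any stage can be re-run or inspected alone.

#' Pipeline configuration
#'
#' @param n cohort size when synthesizing.
#' @param seed master seed; stage seeds are derived from it (cohort: seed,
#'   missingness: seed + 1, imputation: seed + 2).
#' @param cohort_csv optional path to an existing cohort CSV; when given,
#'   the synthesis stage is skipped.
#' @param cohort optional [cohort_config()] override.
#' @param pivots inversion pivots for the detrimental inputs.
#' @param energy_adjust apply residual-method energy adjustment.
#' @param alpha screening significance level.
#' @param input_rule,sign_rule screening rule variants (see
#'   [screen_variables()]).
#' @param rts returns to scale for the DEA stage.
#' @param tobit_covariates covariates for the regression stage.
#' @param tobit_alpha backward-elimination cut-off.
#' @param m,maxit,donors multiple-imputation parameters.
#' @param retain_frac cross-dataset retention threshold.
#' @param lack_top number of most-inefficient DMUs to report.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n = 200, seed = 1L, cohort_csv = NULL,
                            cohort = NULL,
                            pivots = c(alcohol_units = 5.5,
                                       cigarettes_day = 90),
                            energy_adjust = TRUE,
                            alpha = 0.05,
                            input_rule = "any", sign_rule = "majority",
                            rts = "vrs",
                            tobit_covariates = tobit_covariate_columns(),
                            tobit_alpha = 0.05,
                            m = 20, maxit = 50, donors = 5,
                            retain_frac = 0.5,
                            lack_top = 1) {
  stopifnot(is_number(seed), is_number(n), n >= 3)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments (e.g.
#' `n`, `seed`, `alpha`, `m`); unknown keys are rejected. Nested `pivots`
#' mappings are converted to named vectors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare `n` key to boolean false; map it back
  if ("FALSE" %in% names(raw) && !"n" %in% names(raw)) {
    names(raw)[names(raw) == "FALSE"] <- "n"
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(sprintf("unknown pipeline config key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$pivots)) raw$pivots <- unlist(raw$pivots)
  if (!is.null(raw$tobit_covariates)) {
    raw$tobit_covariates <- unlist(raw$tobit_covariates)
  }
  do.call(pipeline_config, raw)
}

#' Run the full gut-microbiota efficiency pipeline
#'
#' Executes every stage in order and writes one artifact set under
#' `out_dir`: the (synthetic) cohort with provenance, the DEA-ready table
#' with transform records, the screening grid and decision, per-DMU scores
#' and summary, lack-of-output reports for the most inefficient DMUs, the
#' pooled univariate and selected multivariate regression tables, VIF
#' diagnostics, and a manifest with seeds and a config hash. Idempotent for
#' a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of class `"gutdea_run"` with the in-memory
#'   stage results (`cohort`, `prep`, `screening`, `dea`, `lack_reports`,
#'   `univariate`, `selection`, `vif`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("gutdea_run_")) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- cohort ---------------------------------------------------------------
  ccfg <- NULL
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      read_cohort(config$cohort_csv)
    } else {
      ccfg <- config$cohort %||% cohort_config(n = config$n,
                                               seed = config$seed)
      tab <- generate_cohort(ccfg)
      counts <- round(unlist(ccfg$missingness) * ccfg$n / 577)
      counts <- pmin(counts, ccfg$n)
      inject_missingness(tab, counts, seed = config$seed + 1L)
    }
  })
  check_cols(cohort, config$tobit_covariates, "cohort")
  write_cohort(cohort, file.path(out_dir, "cohort.csv"), ccfg)

  # -- preprocessing --------------------------------------------------------
  prep <- stage("preprocess", {
    prepare_dea_inputs(cohort, pivots = config$pivots,
                       energy_adjust = config$energy_adjust)
  })
  readr::write_csv(prep$data, file.path(out_dir, "dea_ready.csv"))
  jsonlite::write_json(prep$transforms,
                       file.path(out_dir, "transforms.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)

  # -- screening ------------------------------------------------------------
  screening <- stage("screen", {
    screen_variables(prep$data, prep$inputs, prep$outputs,
                     alpha = config$alpha,
                     input_rule = config$input_rule,
                     sign_rule = config$sign_rule)
  })
  readr::write_csv(screening$grid, file.path(out_dir, "screening_grid.csv"))
  jsonlite::write_json(
    list(kept_inputs = screening$kept_inputs,
         kept_outputs = screening$kept_outputs,
         excluded = screening$excluded),
    file.path(out_dir, "screening_decision.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!length(screening$kept_inputs) || !length(screening$kept_outputs)) {
    abort("pipeline stage 'screen' failed: no inputs or no outputs survived screening")
  }

  # -- DEA ------------------------------------------------------------------
  fit <- stage("dea", {
    dea(prep$data, screening$kept_inputs, screening$kept_outputs,
        id_col = if ("participant_id" %in% names(prep$data))
          "participant_id" else NULL,
        rts = config$rts)
  })
  scores <- tidy(fit)
  scores$peers <- vapply(fit$results$peers, paste, "", collapse = ";")
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  jsonlite::write_json(as.list(glance(fit)),
                       file.path(out_dir, "dea_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # -- lack-of-output reports ----------------------------------------------
  lack_reports <- stage("decompose", {
    worst <- fit$results$dmu[order(fit$results$score)]
    worst <- head(worst, config$lack_top)
    lapply(worst, function(id) lack_report(fit, id, prep$transforms))
  })
  for (lr in lack_reports) {
    base <- file.path(out_dir, sprintf("lack_report_dmu%s", lr$dmu))
    jsonlite::write_json(
      list(dmu = lr$dmu, score = lr$score, phi = lr$phi,
           peers = lr$peers, composite = as.list(lr$composite),
           own = as.list(lr$own), lack = as.list(lr$lack),
           back_transformed = as.list(lr$back_transformed)),
      paste0(base, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(utils::capture.output(print(lr)), paste0(base, ".txt"))
  }

  # -- regression on covariates with MI ------------------------------------
  covars <- config$tobit_covariates
  # constant columns (e.g. a rare-exposure flag with no positives in a small
  # cohort) carry no information and would make the design rank-deficient
  constant <- vapply(covars, function(v) {
    x <- cohort[[v]]
    sd(x[!is.na(x)]) == 0
  }, TRUE)
  if (any(constant)) {
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(covars[constant], collapse = ", ")))
    covars <- covars[!constant]
  }
  reg_tab <- dplyr::bind_cols(cohort[covars],
                              tibble(score = fit$results$score))
  forced <- intersect(c("age", "sex_female", "score",
                        screening$kept_outputs), names(reg_tab))
  reg_tab_full <- dplyr::bind_cols(reg_tab,
                                   cohort[setdiff(screening$kept_outputs,
                                                  names(reg_tab))])
  imputed <- stage("impute", {
    if (anyNA(reg_tab_full)) {
      P <- quickpred(reg_tab_full, forced = forced)
      mice_pmm(reg_tab_full, P, m = config$m, maxit = config$maxit,
               donors = config$donors, seed = config$seed + 2L)
    } else {
      structure(list(imputations = list(reg_tab_full),
                     predictor_matrix = matrix(FALSE, 0, 0), m = 1,
                     maxit = 0, donors = config$donors,
                     seed = config$seed + 2L),
                class = "imputation_set")
    }
  })
  univariate <- stage("regress-univariate", {
    rows <- lapply(covars, function(v) {
      fits <- lapply(imputed$imputations, function(d) {
        fit_tobit(d$score, d[v], lower = 0, upper = 1)
      })
      tab <- if (length(fits) > 1) tidy(pool_rubin(fits)) else tidy(fits[[1]])
      tab <- tab[tab$term == v, intersect(c("term", "estimate", "std.error",
                                            "p.value"), names(tab))]
      tab
    })
    dplyr::bind_rows(rows)
  })
  readr::write_csv(dplyr::mutate(univariate,
                                 estimate_x1000 = .data$estimate * 1000,
                                 std.error_x1000 = .data$std.error * 1000),
                   file.path(out_dir, "regression_univariate.csv"))

  selection <- stage("regress-selection", {
    stepwise_backward_mi(imputed, "score", covars,
                         alpha = config$tobit_alpha,
                         retain_frac = config$retain_frac)
  })
  readr::write_csv(selection$counts,
                   file.path(out_dir, "selection_counts.csv"))
  if (!is.null(selection$pooled)) {
    readr::write_csv(dplyr::mutate(tidy(selection$pooled),
                                   estimate_x1000 = .data$estimate * 1000,
                                   std.error_x1000 = .data$std.error * 1000),
                     file.path(out_dir, "regression_selected.csv"))
  }

  vif_tab <- NULL
  if (length(selection$selected) >= 2) {
    vifs <- vapply(imputed$imputations, function(d) {
      vif(d[selection$selected])
    }, numeric(length(selection$selected)))
    vifs <- matrix(vifs, nrow = length(selection$selected))
    vif_tab <- tibble(variable = selection$selected,
                      mean_vif = rowMeans(vifs))
    readr::write_csv(vif_tab, file.path(out_dir, "vif.csv"))
  }

  manifest <- list(
    package = "gutdea",
    package_version = as.character(utils::packageVersion("gutdea")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = list(cohort = config$seed, missingness = config$seed + 1L,
                       imputation = config$seed + 2L),
    n = nrow(cohort),
    config_hash = rlang::hash(config),
    kept_inputs = screening$kept_inputs,
    kept_outputs = screening$kept_outputs,
    mean_score = mean(fit$results$score),
    fraction_efficient = mean(fit$results$efficient))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(
    list(cohort = cohort, prep = prep, screening = screening, dea = fit,
         lack_reports = lack_reports, univariate = univariate,
         selection = selection, vif = vif_tab, manifest = manifest,
         out_dir = out_dir),
    class = "gutdea_run"))
}

#' @export
print.gutdea_run <- function(x, ...) {
  cat("<gutdea_run>", x$manifest$n, "participants; artifacts in",
      x$out_dir, "\n")
  cat("  inputs: ", paste(x$screening$kept_inputs, collapse = ", "), "\n")
  cat("  outputs:", paste(x$screening$kept_outputs, collapse = ", "), "\n")
  cat(sprintf("  mean score %.3f; fraction efficient %.3f\n",
              x$manifest$mean_score, x$manifest$fraction_efficient))
  cat("  final regression model:",
      if (length(x$selection$selected))
        paste(x$selection$selected, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}
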