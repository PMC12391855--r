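# End-to-end orchestration: simulate (or load) -> impute -> estimate ->
# intervene -> bootstrap -> report.

#' Default pipeline configuration
#'
#' The study configuration: a synthetic cohort of 4196 participants with the
#' calibrated missingness pattern, 50 imputed datasets with 100 chained
#' iterations, the outcome-shift counterfactual, and 1000 bootstrap
#' replicates for 95% intervals. Tests and examples scale `m`, `iterations`
#' and `B` down; every field can be overridden by name.
#'
#' @return A nested list with blocks `generator`, `imputation`, `analysis`,
#'   `bootstrap`, `output` and a master `seed`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    generator = list(n = 4196L, apply_missingness = TRUE, params = NULL),
    input = list(path = NULL),
    imputation = list(m = 50L, iterations = 100L),
    analysis = list(method = "shift", regular_cycle_only = FALSE),
    bootstrap = list(B = 1000L, alpha = 0.05),
    output = list(dir = NULL, write_plot = TRUE)
  )
}

#' Validate a pipeline configuration
#'
#' Schema check run before any computation: unknown blocks or fields,
#' non-numeric sizes, or an `alpha` outside (0, 0.5) are configuration
#' errors. A character scalar is treated as a YAML file path.
#'
#' @param config A config list, or path to a YAML file mirroring
#'   [default_config()].
#' @return The completed config (defaults filled in), invisibly usable.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
            class = "ineqshift_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML file path", class = "ineqshift_config_error")
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config block(s): ", paste(unknown, collapse = ", ")),
          class = "ineqshift_config_error")
  }
  for (blk in names(config)) {
    if (is.list(base[[blk]]) && is.list(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), c(names(base[[blk]]),
                                             names(unclass(default_params(10)))))
      if (length(bad) > 0) {
        abort(sprintf("unknown field(s) in config block '%s': %s",
                      blk, paste(bad, collapse = ", ")),
              class = "ineqshift_config_error")
      }
      base[[blk]][names(config[[blk]])] <- config[[blk]]
    } else {
      base[[blk]] <- config[[blk]]
    }
  }
  with(base, {
    if (!is.numeric(seed)) abort("seed must be numeric", class = "ineqshift_config_error")
    if (!is.numeric(imputation$m) || imputation$m < 1) {
      abort("imputation$m must be a positive count", class = "ineqshift_config_error")
    }
    if (!is.numeric(bootstrap$B) || bootstrap$B < 2) {
      abort("bootstrap$B must be at least 2", class = "ineqshift_config_error")
    }
    if (!is.numeric(bootstrap$alpha) || bootstrap$alpha <= 0 || bootstrap$alpha >= 0.5) {
      abort("bootstrap$alpha must lie in (0, 0.5)", class = "ineqshift_config_error")
    }
    if (!analysis$method %in% c("shift", "predict")) {
      abort("analysis$method must be 'shift' or 'predict'", class = "ineqshift_config_error")
    }
  })
  base
}

#' Run the full inequality-reduction analysis
#'
#' Executes the complete analytic sequence: simulate a cohort (or load one
#' from CSV), blank cells under the MAR mechanism, impute by chained
#' equations, freeze per-predictor reference levels on the observed data,
#' fit the adjusted exposure model on each imputation, estimate each
#' predictor's inequality without and with the hypothetical intervention
#' and its reduction, pool across imputations, and attach
#' percentile-bootstrap confidence intervals (one row resample per
#' replicate, applied identically across imputations). All randomness
#' derives from the single master seed, so reruns with the same
#' configuration reproduce every output.
#'
#' @param config A config list or YAML path, see [default_config()] and
#'   [validate_config()].
#' @return An object of class `ineq_analysis`: `table1`, `table2` (the
#'   with/without/reduction report), `pooled_exposure` (Rubin-pooled
#'   adjusted exposure effect), `positivity`, `references`, `imputed`
#'   metadata, `config`, `seeds`. Written outputs (CSVs, diagnostics JSON,
#'   run manifest, figure) land in `config$output$dir` when set.
#' @export
#' @examples
#' \donttest{
#' cfg <- list(generator = list(n = 600),
#'             imputation = list(m = 3, iterations = 3),
#'             bootstrap = list(B = 50))
#' res <- run_full_analysis(cfg)
#' dplyr::filter(tidy(res), predictor == "education")
#' }
run_full_analysis <- function(config = list()) {
  config <- validate_config(config)
  set.seed(config$seed)
  seeds <- setNames(sample.int(2^30 - 1, 4),
                    c("generator", "missingness", "imputation", "bootstrap"))

  if (!is.null(config$input$path)) {
    observed <- read_cohort_csv(config$input$path)
    params <- NULL
  } else {
    params <- config$generator$params %||% do.call(
      .params_with_overrides, config$generator[setdiff(names(config$generator),
                                                       c("apply_missingness", "params"))])
    cohort <- generate_cohort(params, seed = seeds[["generator"]])
    observed <- if (isTRUE(config$generator$apply_missingness)) {
      apply_missingness(cohort, params, seed = seeds[["missingness"]])
    } else cohort
  }
  if (isTRUE(config$analysis$regular_cycle_only)) {
    observed <- filter_regular_cycle(observed)
  }

  table1 <- make_table1(observed)
  positivity <- tryCatch(check_positivity(observed),
                         error = function(e) conditionMessage(e))

  imputed <- impute_chained(observed, m = config$imputation$m,
                            iterations = config$imputation$iterations,
                            seed = seeds[["imputation"]])

  preds <- intersect(predictor_names(), names(observed))
  references <- vapply(preds, function(p) choose_reference(observed, p),
                       character(1))

  exp_fits <- lapply(imputed$tables, fit_adjusted_exposure_model,
                     predictors = preds, references = references)
  betas <- vapply(exp_fits, function(f) f$exposure_beta, numeric(1))
  beta_vars <- vapply(exp_fits, function(f) {
    f$vcov["early_recognition", "early_recognition"]
  }, numeric(1))
  pooled_exposure <- if (imputed$m >= 2) {
    pool_rubin(betas, beta_vars, alpha = config$bootstrap$alpha)
  } else NULL

  boot <- bootstrap_pipeline(
    imputed,
    estimator = .table2_estimator,
    precompute = function(tb) .table2_state(tb, preds, references,
                                            config$analysis$method),
    B = config$bootstrap$B, alpha = config$bootstrap$alpha,
    seed = seeds[["bootstrap"]])

  table2 <- .assemble_table2(boot, preds, references)
  # self-consistency of the report: reduction == with - without
  chk <- table2$reduction - (table2$beta_with - table2$beta_without)
  stopifnot(all(abs(chk[!is.na(chk)]) < 1e-8))

  result <- structure(list(
    table1 = table1, table2 = table2,
    pooled_exposure = pooled_exposure,
    positivity = positivity,
    references = references,
    bootstrap = boot,
    imputed = list(m = imputed$m, iterations = imputed$iterations,
                   visit_order = imputed$visit_order,
                   n_fallbacks = length(imputed$log)),
    observed = observed,
    config = config, seeds = seeds
  ), class = "ineq_analysis")

  if (!is.null(config$output$dir)) .write_outputs(result)
  result
}

.params_with_overrides <- function(n = 4196L, ...) {
  params <- default_params(n = n)
  overrides <- list(...)
  for (f in names(overrides)) params[[f]] <- overrides[[f]]
  if (length(overrides) > 0) params <- calibrate_params(params)
  params
}

# precomputed numeric state so each bootstrap replicate touches matrices,
# not data frames
.table2_state <- function(tb, preds, references, method) {
  tb <- .as_cohort_factors(tb)
  fml <- as.formula(paste("init_weeks ~ early_recognition +",
                          paste(preds, collapse = " + ")))
  X <- model.matrix(fml, data = tb)
  list(
    X = X, a_col = match("early_recognition", colnames(X)),
    y = tb$init_weeks, a = tb$early_recognition,
    method = method,
    model_frame = if (method == "predict") tb else NULL,
    codes = lapply(tb[preds], as.integer),
    nlev = vapply(tb[preds], nlevels, integer(1)),
    levels = lapply(tb[preds], levels),
    ref_idx = vapply(preds, function(p) {
      match(references[[p]], levels(tb[[p]]))
    }, integer(1)),
    preds = preds)
}

.table2_estimator <- function(state, idx) {
  yv <- state$y[idx]
  fit <- lm.fit(state$X[idx, , drop = FALSE], yv)
  beta_a <- fit$coefficients[state$a_col]
  ystar <- if (!is.na(beta_a)) {
    yv + beta_a * (1 - state$a[idx])
  } else rep(NA_real_, length(yv))

  out <- c(adjusted_exposure_effect = unname(beta_a))
  for (p in state$preds) {
    g <- state$codes[[p]][idx]
    K <- state$nlev[[p]]
    keep <- !is.na(g)
    counts <- tabulate(g[keep], K)
    sums_y <- rep(NA_real_, K); sums_s <- rep(NA_real_, K)
    agg <- rowsum(cbind(yv[keep], ystar[keep]), g[keep])
    present <- as.integer(rownames(agg))
    sums_y[present] <- agg[, 1]; sums_s[present] <- agg[, 2]
    mw <- sums_y / counts
    ms <- sums_s / counts
    r <- state$ref_idx[[p]]
    bw <- mw - mw[r]
    bs <- ms - ms[r]
    lv <- state$levels[[p]]
    vals <- c(bw, bs, bs - bw)
    names(vals) <- c(paste(p, lv, "without", sep = "|"),
                     paste(p, lv, "with", sep = "|"),
                     paste(p, lv, "reduction", sep = "|"))
    out <- c(out, vals)
  }
  out
}

.assemble_table2 <- function(boot, preds, references) {
  rows <- boot[grepl("|", boot$parameter, fixed = TRUE), , drop = FALSE]
  parts <- do.call(rbind, strsplit(rows$parameter, "|", fixed = TRUE))
  rows$predictor <- parts[, 1]
  rows$level <- parts[, 2]
  rows$scenario <- parts[, 3]
  wide <- tidyr::pivot_wider(
    dplyr::select(rows, "predictor", "level", "scenario",
                  "estimate", "conf_low", "conf_high", "flagged"),
    names_from = "scenario",
    values_from = c("estimate", "conf_low", "conf_high", "flagged"))
  out <- tibble::tibble(
    predictor = wide$predictor,
    level = wide$level,
    is_reference = purrr::map2_lgl(wide$predictor, wide$level,
                                   function(p, l) references[[p]] == l),
    beta_without = wide$estimate_without,
    ci_without_low = wide$conf_low_without,
    ci_without_high = wide$conf_high_without,
    beta_with = wide$estimate_with,
    ci_with_low = wide$conf_low_with,
    ci_with_high = wide$conf_high_with,
    reduction = wide$estimate_reduction,
    ci_reduction_low = wide$conf_low_reduction,
    ci_reduction_high = wide$conf_high_reduction,
    flagged = wide$flagged_without | wide$flagged_with | wide$flagged_reduction
  )
  # dictionary ordering within the report
  out$predictor <- factor(out$predictor, levels = preds)
  out <- dplyr::arrange(out, .data$predictor)
  out$predictor <- as.character(out$predictor)
  out
}

.write_outputs <- function(result) {
  dir <- result$config$output$dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$table1, file.path(dir, "table1.csv"), na = "")
  readr::write_csv(result$table2, file.path(dir, "table2.csv"), na = "")
  diagnostics <- list(
    positivity = if (inherits(result$positivity, "propensity_report")) {
      list(minimum = result$positivity$minimum,
           maximum = result$positivity$maximum,
           n = result$positivity$n)
    } else list(error = result$positivity),
    imputation = result$imputed,
    pooled_exposure = if (!is.null(result$pooled_exposure)) {
      list(estimate = result$pooled_exposure$estimate,
           ci = result$pooled_exposure$ci)
    }
  )
  jsonlite::write_json(diagnostics, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(seed = result$config$seed,
                   derived_seeds = as.list(result$seeds),
                   config_hash = rlang::hash(result$config),
                   package_version = as.character(utils::packageVersion("ineqshift")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(result$config$output$write_plot)) {
    ggplot2::ggsave(file.path(dir, "figure1.pdf"), autoplot(result),
                    width = 8, height = 10)
  }
  invisible(dir)
}

#' @export
print.ineq_analysis <- function(x, ...) {
  cat(sprintf("<ineq_analysis: n = %d, m = %d imputations, B = %d bootstrap replicates>\n",
              nrow(x$observed), x$imputed$m, x$config$bootstrap$B))
  if (!is.null(x$pooled_exposure)) {
    cat(sprintf("  adjusted exposure effect: %.2f weeks (%.0f%% CI %.2f, %.2f)\n",
                x$pooled_exposure$estimate,
                100 * (1 - x$config$bootstrap$alpha),
                x$pooled_exposure$ci[1], x$pooled_exposure$ci[2]))
  }
  if (inherits(x$positivity, "propensity_report")) {
    cat(sprintf("  minimum propensity score: %.3f\n", x$positivity$minimum))
  } else {
    cat("  positivity check unavailable:", x$positivity, "\n")
  }
  cat("  report: $table2 (", nrow(x$table2), "rows )\n")
  invisible(x)
}

#' @rdname run_full_analysis
#' @param x An `ineq_analysis`.
#' @param ... Unused.
#' @export
tidy.ineq_analysis <- function(x, ...) x$table2

#' @rdname run_full_analysis
#' @export
glance.ineq_analysis <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$observed), m = x$imputed$m,
    B = x$config$bootstrap$B,
    adjusted_exposure_effect = if (!is.null(x$pooled_exposure)) {
      x$pooled_exposure$estimate
    } else NA_real_,
    min_propensity = if (inherits(x$positivity, "propensity_report")) {
      x$positivity$minimum
    } else NA_real_)
}
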