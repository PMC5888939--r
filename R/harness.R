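#' Monte Carlo experiment configuration
#'
#' Bundles a data-generating process, a per-replication sample size, a
#' replication count, a master seed, and the estimator roster. Each
#' replication draws its own cohort from a sub-seed derived from the master
#' seed (see [derive_seeds()]), so any single replication is re-runnable in
#' isolation.
#'
#' @param dgp A [dgp_config()].
#' @param n_per_rep Cohort size per replication.
#' @param reps Number of replications (default 1000).
#' @param estimators Estimator roster, e.g. from [scenario_estimators()].
#' @param seed Master seed.
#' @param sl_v Super-learner fold count used by TMLE entries (default 10;
#'   the `"scaled"` profile of [run_scenario()] uses 5).
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(dgp, n_per_rep, reps = 1000L, estimators, seed = 1L,
                      sl_v = 10L) {
  stopifnot(inherits(dgp, "dgp_config"), reps >= 1, length(estimators) >= 1)
  structure(
    list(dgp = dgp, n_per_rep = as.integer(n_per_rep),
         reps = as.integer(reps), estimators = estimators,
         seed = as.integer(seed), sl_v = as.integer(sl_v)),
    class = "mc_config"
  )
}

#' Estimator rosters used in the two simulation scenarios
#'
#' Scenario 1 benchmarks the naive estimator against IPTW-RA and AIPTW with
#' correctly specified parametric nuisance models and TMLE with the default
#' super-learner library. Scenario 2 replaces the parametric specs with
#' data-adaptive selection: AIC/BIC best-fit specs for IPTW-RA and AIPTW
#' (the AIPTW weight tolerance relaxed to 1e-8, since best-fit propensity
#' models under severe near-positivity produce extreme scores), and the
#' super learner for TMLE. The naive estimator always uses main terms.
#'
#' @param scenario 1 or 2.
#' @param estimators Subset of `c("naive", "iptw_ra", "aiptw", "tmle")`.
#' @return Named list of estimator configurations for [mc_config()].
#' @export
scenario_estimators <- function(scenario = 1,
                                estimators = c("naive", "iptw_ra", "aiptw",
                                               "tmle")) {
  stopifnot(scenario %in% c(1, 2))
  adaptive <- scenario == 2
  all <- list(
    naive = list(name = "naive", method = "naive",
                 args = list(outcome_spec = model_spec(c("w1", "w2", "w3",
                                                         "w4")))),
    iptw_ra = if (adaptive) {
      list(name = "bf_iptw_ra", method = "iptw_ra", bfit = TRUE,
           args = list())
    } else {
      list(name = "iptw_ra", method = "iptw_ra",
           args = list(treatment_spec = spec_preset(1, "treatment"),
                       outcome_spec = spec_preset(1, "outcome")))
    },
    aiptw = if (adaptive) {
      list(name = "bf_aiptw", method = "aiptw", bfit = TRUE,
           args = list(ps_tol = 1e-8))
    } else {
      list(name = "aiptw", method = "aiptw",
           args = list(treatment_spec = spec_preset(1, "treatment"),
                       outcome_spec = spec_preset(1, "outcome")))
    },
    tmle = list(name = "tmle", method = "tmle",
                args = list(nuisance = "superlearner"))
  )
  out <- all[estimators]
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

apply_estimator <- function(est, cohort, rep_seed, sl_v) {
  args <- est$args %||% list()
  if (isTRUE(est$bfit)) {
    crit <- est$criterion %||% "aic"
    args$treatment_spec <- chosen_spec(bfit_select(cohort, "a",
                                                   criterion = crit))
    args$outcome_spec <- chosen_spec(bfit_select(cohort, "y",
                                                 criterion = crit))
  }
  if (est$method == "tmle") {
    args$seed <- rep_seed
    if (is.null(args$sl_v)) args$sl_v <- sl_v
  }
  do.call(estimate_ate, c(list(data = cohort, method = est$method), args))
}

#' Run one Monte Carlo replication
#'
#' Generates the replication's cohort from its derived sub-seed and applies
#' every configured estimator. Estimator failures (positivity errors,
#' non-convergence, empty arms) are captured per estimator — recorded in
#' the `error` column — and never abort the replication.
#'
#' @param config An [mc_config()].
#' @param rep_index Replication number in `1..reps`.
#' @return Tibble with one row per estimator: `rep`, `estimator`, `psi`,
#'   `se`, `conf.low`, `conf.high`, `error`.
#' @export
run_replicate <- function(config, rep_index) {
  stopifnot(inherits(config, "mc_config"),
            rep_index >= 1, rep_index <= config$reps)
  rep_seed <- derive_seeds(config$seed, config$reps)[rep_index]
  cohort <- generate_cohort(config$dgp, config$n_per_rep, seed = rep_seed)
  purrr::map_dfr(config$estimators, function(est) {
    res <- tryCatch(
      apply_estimator(est, cohort, rep_seed, config$sl_v),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(rep = rep_index, estimator = est$name,
                     psi = NA_real_, se = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     error = conditionMessage(res))
    } else {
      tibble::tibble(rep = rep_index, estimator = est$name,
                     psi = res$psi, se = res$se,
                     conf.low = unname(res$ci95[1]),
                     conf.high = unname(res$ci95[2]),
                     error = NA_character_)
    }
  })
}

#' Aggregate per-replication estimates into performance metrics
#'
#' For each estimator: the mean and SD of the estimates across
#' replications, absolute bias `|mean - psi0|`, relative bias
#' `100 |mean - psi0| / |psi0|`, `rmse = sqrt(mean((psi_r - psi0)^2))`, and
#' the percentage of replications whose 95% CI contains `psi0`. Failed
#' replications are excluded from the metrics and counted in `n_failed`;
#' an estimator with more than 20% failures is flagged `unreliable`.
#'
#' @param raw Per-replication tibble as produced by [run_replicate()].
#' @param psi0 True risk difference.
#' @return Tibble with one row per estimator.
#' @export
performance_summary <- function(raw, psi0) {
  raw |>
    dplyr::group_by(estimator = factor(.data$estimator,
                                       levels = unique(raw$estimator))) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_failed = sum(is.na(.data$psi)),
      mean_psi = mean(.data$psi, na.rm = TRUE),
      sd_psi = sd(.data$psi, na.rm = TRUE),
      abs_bias = abs(.data$mean_psi - psi0),
      rel_bias_pct = 100 * .data$abs_bias / abs(psi0),
      rmse = sqrt(mean((.data$psi - psi0)^2, na.rm = TRUE)),
      coverage_pct = 100 * mean(.data$conf.low <= psi0 &
                                  psi0 <= .data$conf.high, na.rm = TRUE),
      unreliable = .data$n_failed > 0.2 * .data$n_reps,
      .groups = "drop"
    ) |>
    dplyr::mutate(estimator = as.character(.data$estimator))
}

#' Run the full Monte Carlo experiment
#'
#' Computes the true risk difference by the plug-in method
#' ([compute_true_ate()]), runs every replication, and aggregates with
#' [performance_summary()].
#'
#' @param config An [mc_config()].
#' @param true_ate_n_mc Covariate draws for the plug-in truth (default
#'   1e6).
#' @param progress Print a dot every 50 replications.
#' @return Object of class `mc_result`: list with `summary` (the metrics
#'   tibble), `raw` (per-replication estimates), `psi0` and `config`.
#' @export
run_monte_carlo <- function(config, true_ate_n_mc = 1e6, progress = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  psi0 <- compute_true_ate(config$dgp, n_mc = true_ate_n_mc,
                           seed = config$seed + 1L)
  raw <- purrr::map_dfr(seq_len(config$reps), function(r) {
    if (progress && r %% 50 == 0) cat(".")
    run_replicate(config, r)
  })
  if (progress) cat("\n")
  structure(
    list(summary = performance_summary(raw, psi0), raw = raw,
         psi0 = psi0, config = config),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo benchmark: %d reps, n = %d, true ATE = %.4f\n",
              x$config$reps, x$config$n_per_rep, x$psi0))
  print(report_table(x))
  invisible(x)
}

#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) x$summary

#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(reps = x$config$reps, n_per_rep = x$config$n_per_rep,
                 psi0 = x$psi0,
                 n_estimators = length(x$config$estimators))
}

#' Benchmark-table formatting and export
#'
#' Formats a summary in the benchmark-table layout — `ATE (SD)`, absolute
#' bias (4 decimals), relative bias (1 decimal, percent), RMSE (4
#' decimals), coverage (1 decimal, percent) — and optionally writes CSV
#' (unformatted numeric columns, so a read-back preserves the values) and
#' plain text.
#'
#' @param x An `mc_result` or the summary tibble itself.
#' @param csv,txt Optional output file paths.
#' @return The formatted tibble, invisibly the same as printed.
#' @export
report_table <- function(x, csv = NULL, txt = NULL) {
  summary <- if (inherits(x, "mc_result")) x$summary else x
  fmt <- tibble::tibble(
    estimator = summary$estimator,
    `ATE (SD)` = sprintf("%.4f (%.3f)", summary$mean_psi, summary$sd_psi),
    `Absolute bias` = sprintf("%.4f", summary$abs_bias),
    `Relative bias, %` = sprintf("%.1f", summary$rel_bias_pct),
    RMSE = sprintf("%.4f", summary$rmse),
    `Coverage, %` = sprintf("%.1f", summary$coverage_pct),
    Failed = summary$n_failed
  )
  if (nrow(fmt) > 0 && any(summary$unreliable)) {
    fmt$estimator[summary$unreliable] <-
      paste0(fmt$estimator[summary$unreliable], " [unreliable]")
  }
  if (!is.null(csv)) {
    write.csv(summary, csv, row.names = FALSE)
  }
  if (!is.null(txt)) {
    writeLines(c(
      paste(names(fmt), collapse = "\t"),
      apply(fmt, 1, paste, collapse = "\t")
    ), txt)
  }
  fmt
}

#' @describeIn run_monte_carlo Sampling distributions of the estimators
#'   with the true value marked.
#' @param object An `mc_result`.
#' @param ... Unused.
#' @method autoplot mc_result
#' @export
autoplot.mc_result <- function(object, ...) {
  raw <- dplyr::filter(object$raw, !is.na(.data$psi))
  ggplot2::ggplot(raw, ggplot2::aes(x = .data$psi, fill = .data$estimator)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.9) +
    ggplot2::facet_wrap(~estimator, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$psi0, linetype = 2) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "estimated risk difference",
                  y = "replications",
                  title = sprintf("True ATE = %.4f", object$psi0)) +
    ggplot2::theme_minimal()
}

#' Run a scenario benchmark with the paper-style or desk-scale profile
#'
#' Convenience wrapper tying together the scenario DGP presets, the
#' scenario estimator rosters, and [run_monte_carlo()]. The `"full"`
#' profile uses 1,000 replications and 10-fold super-learner
#' cross-validation; `"scaled"` uses 200 replications and 5 folds, sized
#' for interactive desk runs.
#'
#' @param scenario 1 or 2.
#' @param n Cohort size per replication (1000 or 10000 in the benchmark).
#' @param profile `"scaled"` (default) or `"full"`.
#' @param seed Master seed.
#' @param estimators Subset passed to [scenario_estimators()].
#' @param reps Optional replication-count override.
#' @return An `mc_result`.
#' @export
run_scenario <- function(scenario = 1, n = 1000, profile = c("scaled",
                                                             "full"),
                         seed = 1L, estimators = c("naive", "iptw_ra",
                                                   "aiptw", "tmle"),
                         reps = NULL) {
  profile <- match.arg(profile)
  reps <- reps %||% if (profile == "full") 1000L else 200L
  sl_v <- if (profile == "full") 10L else 5L
  dgp <- if (scenario == 1) dgp_scenario1() else dgp_scenario2()
  cfg <- mc_config(dgp, n_per_rep = n, reps = reps,
                   estimators = scenario_estimators(scenario, estimators),
                   seed = seed, sl_v = sl_v)
  run_monte_carlo(cfg)
}
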