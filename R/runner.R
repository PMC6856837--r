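## Orchestration of the factorial Monte Carlo experiment: scenario x missing
## rate x adjustment method x approach, with deterministic per-replicate
## seeding, CSV/JSON outputs and summary figures.

# Study-design pairing of adjustment method to exposure prevalence: IPTW and
# stratification target the population effect and run on 50%-exposed data;
# SMRW and matching target the effect in the exposed and run on 10%-exposed
# data. With no effect heterogeneity all four target the same true value.
.method_prevalence <- c(IPTW = 0.5, STRAT = 0.5, SMRW = 0.1, MATCH = 0.1)

#' Build a run configuration
#'
#' @param scenarios character vector of scenario ids (`"S1"`..`"S8"`).
#' @param missing_rates numeric vector of target missingness proportions.
#' @param methods subset of `c("IPTW", "SMRW", "MATCH", "STRAT")`.
#' @param approaches subset of `c("ACROSS", "WITHIN")`.
#' @param n,m,n_reps,n_cycles dataset size, imputations per dataset,
#'   replicates per cell, chained-equation cycles.
#' @param master_seed integer master seed; replicate seeds derive from it via
#'   [derive_seed()].
#' @param output_dir directory for CSV/JSON outputs, or `NULL` to skip writing.
#' @param mcsd_convention passed to [summarize_performance()].
#' @param n_mc_calibration Monte Carlo sample size for intercept calibration.
#' @param allow_any_pairing if `TRUE`, do not enforce the method-prevalence
#'   pairing (exploration only); methods then run at `default_prevalence`.
#' @param default_prevalence prevalence used when pairing is not enforced.
#' @param write_replicates write the per-replicate long CSV as well.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenarios = "S1",
                       missing_rates = 0.25,
                       methods = c("IPTW"),
                       approaches = c("ACROSS", "WITHIN"),
                       n = 1000L, m = 10L, n_reps = 200L, n_cycles = 10L,
                       master_seed = 20190911L,
                       output_dir = NULL,
                       mcsd_convention = "about_mean",
                       n_mc_calibration = 1e6,
                       allow_any_pairing = FALSE,
                       default_prevalence = 0.5,
                       write_replicates = TRUE) {
  methods <- match.arg(methods, c("IPTW", "SMRW", "MATCH", "STRAT"),
                       several.ok = TRUE)
  approaches <- match.arg(approaches, c("ACROSS", "WITHIN"), several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run one simulation replicate
#'
#' Generates one observed dataset under the calibrated scenario, imputes,
#' builds the propensity-score stack, and computes the requested
#' method-by-approach estimates.
#'
#' @param spec a calibrated `scenario_spec`.
#' @param methods,approaches which estimators to compute.
#' @param seed replicate seed (set before data generation; also seeds the
#'   matching order).
#' @param m,n_cycles imputation settings.
#' @return a data frame, one row per method x approach.
#' @export
run_replicate <- function(spec, methods, approaches, seed,
                          m = spec$m, n_cycles = 10L) {
  set.seed(seed)
  obs <- simulate_observed(spec)
  stack <- mice_impute(obs, m = m, n_cycles = n_cycles)
  ps <- build_ps_stack(stack, spec$confounders)
  scale <- if (spec$outcome_type == "continuous") "difference" else "logRR"
  opts <- list(match_seed = seed)
  rows <- list()
  for (method in methods) {
    for (approach in approaches) {
      est <- if (approach == "WITHIN") {
        within_estimate(ps, stack, method, scale, opts)
      } else {
        across_estimate(ps, stack, method, scale, opts)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, method = method, approach = approach,
        estimate = est$estimate, se = est$se, df = est$df,
        ci_low = est$ci_low, ci_high = est$ci_high,
        within_variance = est$within_variance,
        between_variance = est$between_variance, scale = scale
      )
    }
  }
  do.call(rbind, rows)
}

# Deduplicated (scenario, prevalence, missing rate) groups, in deterministic
# order; each group shares one calibrated spec and one stream of replicates.
.grid_groups <- function(config, prevalences) {
  groups <- unique(expand.grid(
    scenario = config$scenarios,
    prevalence = unname(prevalences),
    missing_rate = config$missing_rates,
    stringsAsFactors = FALSE))
  groups[order(groups$scenario, groups$prevalence,
               groups$missing_rate), , drop = FALSE]
}

# Full cell enumeration (scenario x rate x method x approach) implied by a
# config, with the method-prevalence pairing applied.
grid_cells <- function(config) {
  prevalences <- if (config$allow_any_pairing) {
    stats::setNames(rep(config$default_prevalence, length(config$methods)),
                    config$methods)
  } else {
    .method_prevalence[config$methods]
  }
  cells <- expand.grid(scenario = config$scenarios,
                       missing_rate = config$missing_rates,
                       method = config$methods,
                       approach = config$approaches,
                       stringsAsFactors = FALSE)
  cells$prevalence <- unname(prevalences[cells$method])
  cells
}

#' Run the full experimental grid
#'
#' Enumerates scenario x missing-rate x method x approach cells (with the
#' method-prevalence pairing of the study design), calibrates each scenario
#' setting once, runs `n_reps` seeded replicates per setting, and aggregates
#' into one performance-summary row per cell. Replicates that fail (e.g. no
#' admissible matches) are logged with their seed and excluded.
#'
#' @param config a `run_config`.
#' @return list with `summary` (one row per cell), `replicates` (long format),
#'   `failures`; written as CSV/JSON under `config$output_dir` when set.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prevalences <- if (config$allow_any_pairing) {
    stats::setNames(rep(config$default_prevalence, length(config$methods)),
                    config$methods)
  } else {
    .method_prevalence[config$methods]
  }
  # group cells sharing a calibrated spec and simulated data
  groups <- .grid_groups(config, prevalences)

  summary_rows <- list(); rep_rows <- list(); failures <- list()
  for (g in seq_len(nrow(groups))) {
    sc <- groups$scenario[g]
    prev <- groups$prevalence[g]
    rate <- groups$missing_rate[g]
    methods_here <- config$methods[prevalences[config$methods] == prev]
    spec <- make_scenario(sc, exposure_prevalence_target = prev,
                          missing_rate_target = rate,
                          n = config$n, m = config$m, n_reps = config$n_reps)
    set.seed(derive_seed(config$master_seed, 0L, stream = g))
    spec <- calibrate_scenario(spec, n_mc = config$n_mc_calibration)
    truth <- true_effect(spec)

    reps <- list()
    for (k in seq_len(config$n_reps)) {
      seed_k <- derive_seed(config$master_seed, k, stream = g)
      res <- tryCatch(
        run_replicate(spec, methods_here, config$approaches, seed_k,
                      m = config$m, n_cycles = config$n_cycles),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          scenario = sc, missing_rate = rate, seed = seed_k,
          reason = conditionMessage(res))
      } else {
        res$replicate <- k
        reps[[length(reps) + 1L]] <- res
      }
    }
    if (length(reps) == 0) next
    long <- do.call(rbind, reps)
    long$scenario <- sc
    long$missing_rate <- rate
    long$prevalence <- prev
    rep_rows[[g]] <- long

    for (method in methods_here) {
      for (approach in config$approaches) {
        cell <- long[long$method == method & long$approach == approach, ]
        s <- summarize_performance(cell, truth, config$mcsd_convention)
        summary_rows[[length(summary_rows) + 1L]] <- cbind(
          data.frame(scenario = sc, approach = approach, method = method,
                     missing_rate = rate, prevalence = prev), s)
      }
    }
  }
  out <- list(summary = do.call(rbind, summary_rows),
              replicates = do.call(rbind, rep_rows),
              failures = if (length(failures)) do.call(rbind, failures) else
                data.frame())
  if (!is.null(config$output_dir)) .write_grid_outputs(out, config)
  out
}

.write_grid_outputs <- function(out, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(config$output_dir, ...)
  utils::write.csv(out$summary, f("summary.csv"), row.names = FALSE)
  if (isTRUE(config$write_replicates)) {
    utils::write.csv(out$replicates, f("replicates.csv"), row.names = FALSE)
  }
  if (nrow(out$failures)) {
    utils::write.csv(out$failures, f("failures.csv"), row.names = FALSE)
  }
  manifest <- config[setdiff(names(config), "output_dir")]
  manifest$package_version <- as.character(utils::packageVersion("miprop"))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out)
}

#' Plot a performance metric against the missingness rate
#'
#' One panel per scenario, percent missing on the x axis, one line per
#' approach-method combination. `metric = "se"` overlays the average
#' model-based SE (solid) and the Monte Carlo SD (dashed) to show SE
#' calibration; `"coverage_pct"` adds a horizontal reference at the nominal
#' 95% level; `"bias"` adds a reference at zero.
#'
#' @param summary the summary data frame from [run_grid()].
#' @param metric one of `"bias"`, `"mse"`, `"mcsd"`, `"avg_se"`,
#'   `"coverage_pct"`, `"se"`.
#' @param file optional path; when given the figure is saved there.
#' @return the ggplot object, invisibly.
#' @export
plot_results <- function(summary, metric = c("bias", "mse", "mcsd", "avg_se",
                                             "coverage_pct", "se"),
                         file = NULL) {
  metric <- match.arg(metric)
  if (is.null(summary) || nrow(summary) == 0) {
    stop("empty results table", call. = FALSE)
  }
  summary$pct_missing <- 100 * summary$missing_rate
  summary$series <- paste(summary$approach, summary$method, sep = " / ")
  if (metric == "se") {
    p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$pct_missing,
                                               colour = .data$series)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$avg_se, linetype = "SE")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mcsd, linetype = "MCSD")) +
      ggplot2::labs(y = "SE / MCSD", linetype = NULL)
  } else {
    p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$pct_missing,
                                               y = .data[[metric]],
                                               colour = .data$series)) +
      ggplot2::geom_line() + ggplot2::geom_point()
    if (metric == "coverage_pct") {
      p <- p + ggplot2::geom_hline(yintercept = 95, linetype = "dotted")
    }
    if (metric == "bias") {
      p <- p + ggplot2::geom_hline(yintercept = 0, linetype = "dotted")
    }
  }
  p <- p + ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "% missing", colour = "approach / method") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 6)
  invisible(p)
}
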