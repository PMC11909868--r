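# Deterministic sensitivity analyses: one-way sweeps, tornado summaries,
# threshold searches, and scenario PSA runs. Deterministic analyses hold
# every other parameter at its base value, which is what reproduces the
# published endpoint arithmetic (e.g. diagnostic-cost deltas at referral
# rates 0 and 1).

sweep_metrics <- function() {
  c("total_cost", "diagnostic_cost", "qalys", "nmb")
}

extract_metric <- function(results, metric, wtp = NULL) {
  switch(metric,
    total_cost = results$total_cost,
    diagnostic_cost = results$cost_supplemental + results$cost_biopsy,
    qalys = results$qalys,
    nmb = {
      if (is.null(wtp)) {
        rlang::abort("metric 'nmb' needs a `wtp` value.")
      }
      nmb(results$total_cost, results$qalys, wtp)
    },
    rlang::abort(paste0("Unknown metric: ", metric))
  )
}

#' One-way sensitivity sweep
#'
#' Varies a single parameter over a grid within its sensitivity range while
#' holding every other parameter at its base value, and evaluates a metric
#' for all four strategies at each grid point.
#'
#' @inheritParams run_psa
#' @param param Name of a registry parameter.
#' @param grid Numeric vector of values within the parameter's
#'   `[low, high]` range; default is 21 equally spaced points.
#' @param metric One of `"total_cost"`, `"diagnostic_cost"` (supplemental
#'   diagnostics plus biopsy costs), `"qalys"`, `"nmb"`.
#' @param wtp Willingness-to-pay ($/QALY), required for `metric = "nmb"`.
#'
#' @return A tibble of class `cea_sweep` with columns `param`, `value`,
#'   `strategy`, `metric`, `result`.
#' @examples
#' one_way_sweep(default_registry(), "p_referral",
#'               grid = c(0, 1), metric = "diagnostic_cost")
#' @export
one_way_sweep <- function(registry, param, grid = NULL,
                          metric = c("total_cost", "diagnostic_cost",
                                     "qalys", "nmb"),
                          wtp = NULL, scenario = cea_scenario()) {
  registry <- as_registry(registry)
  metric <- rlang::arg_match(metric)
  row <- registry[registry$name == param, ]
  if (nrow(row) == 0) {
    rlang::abort(paste0("Unknown parameter: ", param))
  }
  if (is.null(grid)) {
    grid <- seq(row$low, row$high, length.out = 21)
  }
  if (any(grid < row$low - 1e-12) || any(grid > row$high + 1e-12)) {
    rlang::abort(paste0(
      "Grid values outside the sensitivity range [", row$low, ", ",
      row$high, "] of ", param
    ))
  }
  base <- realize_parameters(registry, "base")
  params <- base[rep(1, length(grid)), ]
  params[[param]] <- grid
  params$.draw <- seq_along(grid)
  results <- evaluate_all(params, scenario)
  metric_values <- extract_metric(results, metric, wtp)
  out <- tibble::tibble(
    param = param,
    value = grid[results$.draw],
    strategy = results$strategy,
    metric = metric,
    result = metric_values
  )
  class(out) <- c("cea_sweep", class(out))
  out
}

#' Tornado summary of one-way sensitivity
#'
#' Evaluates the chosen metric at each parameter's lower and upper
#' sensitivity bound (all other parameters at base values) and ranks
#' parameters by the span of the metric, per strategy.
#'
#' @inheritParams one_way_sweep
#' @param params Which registry parameters to include; defaults to every
#'   parameter with a nondegenerate range.
#' @return A tibble of class `cea_tornado` with columns `strategy`,
#'   `param`, `at_low`, `at_high`, `span`, arranged by decreasing span
#'   within strategy.
#' @examples
#' tornado(default_registry(), metric = "total_cost") |>
#'   dplyr::filter(strategy == "ml_algorithm")
#' @export
tornado <- function(registry, metric = c("total_cost", "diagnostic_cost",
                                         "qalys", "nmb"),
                    wtp = NULL, params = NULL, scenario = cea_scenario()) {
  registry <- as_registry(registry)
  metric <- rlang::arg_match(metric)
  if (is.null(params)) {
    params <- registry$name[registry$low < registry$high]
  }
  out <- purrr::map_dfr(params, function(pm) {
    row <- registry[registry$name == pm, ]
    sw <- one_way_sweep(registry, pm, grid = c(row$low, row$high),
                        metric = metric, wtp = wtp, scenario = scenario)
    sw |>
      tidyr::pivot_wider(
        id_cols = c("param", "strategy"),
        names_from = "value", values_from = "result"
      ) |>
      stats::setNames(c("param", "strategy", "at_low", "at_high"))
  })
  out <- out |>
    dplyr::mutate(span = abs(.data$at_high - .data$at_low)) |>
    dplyr::arrange(.data$strategy, dplyr::desc(.data$span))
  class(out) <- c("cea_tornado", class(out))
  out
}

#' Threshold search on a single parameter
#'
#' Finds the parameter value at which a named strategy becomes (or ceases
#' to be) the net-monetary-benefit-optimal strategy at a stated
#' willingness-to-pay, all other parameters held at base values. The
#' criterion is bisected over the parameter's sensitivity range; the
#' returned threshold is verified by evaluating the criterion on both
#' sides.
#'
#' @inheritParams one_way_sweep
#' @param strategy Strategy whose optimality defines the criterion.
#' @param wtp Willingness-to-pay ($/QALY) at which NMB is compared.
#' @param tolerance Bisection tolerance on the parameter value (default $1
#'   for costs, 1e-4 for probabilities).
#'
#' @return A one-row tibble: `param`, `criterion`, `found`, `threshold`,
#'   `bracket_low`, `bracket_high`, `optimal_below`, `optimal_above`. When
#'   the criterion does not change over the range, `found` is `FALSE` and
#'   the threshold is `NA` (not an error).
#' @examples
#' threshold_search(default_registry(), "c_treat",
#'                  strategy = "treat_all", wtp = 150000)
#' @export
threshold_search <- function(registry, param, strategy, wtp,
                             tolerance = NULL, scenario = cea_scenario()) {
  registry <- as_registry(registry)
  if (!(strategy %in% strategy_ids())) {
    rlang::abort(paste0("Unknown strategy: ", strategy))
  }
  row <- registry[registry$name == param, ]
  if (nrow(row) == 0) rlang::abort(paste0("Unknown parameter: ", param))
  if (is.null(tolerance)) {
    tolerance <- if (param %in% probability_symbols()) 1e-4 else 1
  }
  base <- realize_parameters(registry, "base")

  optimal_at <- function(x) {
    p <- base
    p[[param]] <- x
    res <- evaluate_all(p, scenario)
    b <- nmb(res$total_cost, res$qalys, wtp)
    res$strategy[which.max(b)]
  }
  crit <- function(x) optimal_at(x) == strategy

  lo <- row$low
  hi <- row$high
  f_lo <- crit(lo)
  f_hi <- crit(hi)
  if (f_lo == f_hi) {
    return(tibble::tibble(
      param = param, criterion = paste0(strategy, " optimal at wtp=", wtp),
      found = FALSE, threshold = NA_real_,
      bracket_low = lo, bracket_high = hi,
      optimal_below = optimal_at(lo), optimal_above = optimal_at(hi)
    ))
  }
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (crit(mid) == f_lo) lo <- mid else hi <- mid
  }
  threshold <- (lo + hi) / 2
  tibble::tibble(
    param = param, criterion = paste0(strategy, " optimal at wtp=", wtp),
    found = TRUE, threshold = threshold,
    bracket_low = lo, bracket_high = hi,
    optimal_below = optimal_at(threshold - tolerance),
    optimal_above = optimal_at(threshold + tolerance)
  )
}

#' Scenario analyses
#'
#' Runs a full PSA and efficiency frontier under each scenario, using the
#' same seed throughout so scenarios differ only through their settings
#' (e.g. 25% and 50% reductions in lifetime treatment cost).
#'
#' @inheritParams run_psa
#' @param scenarios A named list of [cea_scenario()] objects.
#'
#' @return A tibble with one row per scenario and list-columns `psa`
#'   (`cea_psa`), `summary` (per-strategy means and intervals) and
#'   `frontier` (`cea_frontier` on the PSA means).
#' @examples
#' run_scenarios(
#'   default_registry(),
#'   scenarios = list(
#'     base = cea_scenario(),
#'     half_cost = cea_scenario(treat_cost_multiplier = 0.5)
#'   ),
#'   n = 200, seed = 1
#' )
#' @export
run_scenarios <- function(registry, scenarios, n = 10000, seed = NULL) {
  registry <- as_registry(registry)
  if (!is.list(scenarios) || length(scenarios) == 0) {
    rlang::abort("`scenarios` must be a nonempty named list of cea_scenario.")
  }
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    rlang::abort("`scenarios` must be named.")
  }
  rows <- purrr::imap(scenarios, function(sc, nm) {
    psa <- run_psa(registry, n = n, seed = seed, scenario = sc)
    summ <- tidy(psa)
    fr <- icer_frontier(
      summ |> dplyr::select("strategy", "cost", qaly = "qalys")
    )
    tibble::tibble(
      scenario = nm, psa = list(psa), summary = list(summ),
      frontier = list(fr)
    )
  })
  dplyr::bind_rows(rows)
}
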