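#' Patient-level microsimulation of the diagnostic pathways
#'
#' Simulates individual patients through the same decision tree the cohort
#' model evaluates analytically: disease status, first-line test result,
#' biopsy referral, biopsy death and biopsy classification are each
#' resolved by an independent Bernoulli draw, and the patient receives
#' exactly the pathway payoffs of [enumerate_pathways()]. Empirical cohort
#' means therefore converge to [evaluate_strategy()] at rate 1/sqrt(n),
#' which makes the microsimulation a brute-force check on the cohort
#' algebra (see [compare_to_analytic()]).
#'
#' @param params A single parameter set (one-row data frame or named list).
#' @param strategy One of [strategy_ids()].
#' @param n Number of patients.
#' @param seed Integer seed; patient-level simulation should be seeded
#'   independently of any PSA run.
#' @param scenario A [cea_scenario()].
#'
#' @return A tibble with one row per patient: `id`, `has_ipf`,
#'   `test_result`, `biopsied`, `died_biopsy`, `state`, `cost`, `qaly`.
#' @examples
#' realize_parameters(default_registry(), "base") |>
#'   simulate_cohort("ml_algorithm", n = 10, seed = 1)
#' @export
simulate_cohort <- function(params, strategy, n, seed = NULL,
                            scenario = cea_scenario()) {
  if (!(strategy %in% strategy_ids())) {
    rlang::abort(paste0("Unknown strategy: ", strategy))
  }
  p <- as_param_list(params)
  if (any(lengths(p) != 1L)) {
    rlang::abort("`simulate_cohort()` takes a single parameter set.")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rlang::abort("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  arm <- arm_settings(p, strategy, scenario)

  sim <- function() {
    has_ipf <- stats::runif(n) < p$prevalence
    test_result <- rep("none", n)
    biopsied <- rep(FALSE, n)
    died <- rep(FALSE, n)
    treated <- rep(FALSE, n)

    if (strategy %in% c("ml_algorithm", "genomic_classifier")) {
      if (strategy == "ml_algorithm") {
        s <- p$sens_algo; cs <- p$spec_algo
      } else {
        s <- p$sens_gc; cs <- p$spec_gc
      }
      positive <- stats::runif(n) < ifelse(has_ipf, s, 1 - cs)
      test_result <- ifelse(positive, "positive", "inconclusive")
      referred <- !positive & (stats::runif(n) < p$p_referral)
      treated_emp <- !positive & !referred &
        (stats::runif(n) < scenario$p_inconclusive_treat)
      biopsied <- referred
      died <- biopsied & (stats::runif(n) < p$p_biopsy_death)
      survivor <- biopsied & !died
      classified_pos <- survivor &
        (stats::runif(n) < ifelse(has_ipf, p$sens_biopsy, 1 - p$spec_biopsy))
      treated <- positive | treated_emp | classified_pos
    } else if (strategy == "biopsy_all") {
      biopsied <- rep(TRUE, n)
      died <- stats::runif(n) < p$p_biopsy_death
      survivor <- !died
      treated <- survivor &
        (stats::runif(n) < ifelse(has_ipf, p$sens_biopsy, 1 - p$spec_biopsy))
    } else { # treat_all
      treated <- rep(TRUE, n)
    }

    state <- dplyr::case_when(
      died ~ "death",
      treated & has_ipf ~ "TP",
      treated & !has_ipf ~ "FP",
      !treated & has_ipf ~ "FN",
      TRUE ~ "TN"
    )
    # false-positive treatment benefit is a per-patient Bernoulli here,
    # matching the cohort model's expected upgrade
    fp_upgraded <- state == "FP" & (stats::runif(n) < arm$fp_benefit)

    cost <- arm$fee +
      ifelse(biopsied, p$c_slb, 0) +
      ifelse(state %in% c("TP", "FP"), p$c_treat * scenario$treat_cost_multiplier, 0) +
      ifelse(state %in% c("TN", "FN"), p$c_symptom, 0)
    q_state <- dplyr::case_when(
      state == "death" ~ 0,
      state == "TP" ~ p$q_tp,
      fp_upgraded ~ p$q_tp,
      state == "FP" ~ p$q_fp,
      state == "TN" ~ p$q_tn,
      TRUE ~ p$q_fn
    )
    qaly <- ifelse(
      state == "death", 0,
      q_state -
        ifelse(biopsied & !died, p$u_biopsy, 0) -
        ifelse(state %in% c("TP", "FP"), p$u_complication, 0)
    )

    tibble::tibble(
      id = seq_len(n), strategy = strategy, has_ipf = has_ipf,
      test_result = test_result, biopsied = biopsied, died_biopsy = died,
      state = state, cost = cost, qaly = qaly
    )
  }
  if (is.null(seed)) sim() else withr::with_seed(as.integer(seed), sim())
}

#' Summarize a simulated cohort
#'
#' Empirical means with standard errors for cost, QALYs and terminal-state
#' frequencies, in a long format aligned with the analytic quantities of
#' [evaluate_strategy()].
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return A tibble with columns `quantity`, `estimate`, `se`, plus the
#'   cohort size as attribute `n`.
#' @export
cohort_summary <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0) rlang::abort("Empty cohort.")
  prop <- function(x) {
    p <- mean(x)
    tibble::tibble(estimate = p, se = sqrt(p * (1 - p) / n))
  }
  mean_se <- function(x) {
    tibble::tibble(estimate = mean(x), se = stats::sd(x) / sqrt(n))
  }
  out <- dplyr::bind_rows(
    dplyr::bind_cols(quantity = "total_cost", mean_se(cohort$cost)),
    dplyr::bind_cols(quantity = "qalys", mean_se(cohort$qaly)),
    dplyr::bind_cols(quantity = "p_tp", prop(cohort$state == "TP")),
    dplyr::bind_cols(quantity = "p_fp", prop(cohort$state == "FP")),
    dplyr::bind_cols(quantity = "p_tn", prop(cohort$state == "TN")),
    dplyr::bind_cols(quantity = "p_fn", prop(cohort$state == "FN")),
    dplyr::bind_cols(quantity = "p_biopsy_death", prop(cohort$state == "death")),
    dplyr::bind_cols(quantity = "p_biopsied", prop(cohort$biopsied))
  )
  attr(out, "n") <- n
  out
}

#' Compare a simulated cohort with the analytic cohort expectation
#'
#' Computes z-scores `(empirical - analytic) / SE` for every quantity the
#' two representations share. Quantities with zero sampling variance are
#' compared exactly. The comparison passes when every |z| is at most
#' `z_max` (default 4) and every zero-variance quantity matches exactly.
#'
#' @param summary A [cohort_summary()] of a cohort simulated under the same
#'   parameters, strategy and scenario as `analytic`.
#' @param analytic A one-row [evaluate_strategy()] result.
#' @param z_max Pass threshold on |z|.
#' @return A tibble with columns `quantity`, `empirical`, `analytic`, `se`,
#'   `z`, `pass`, and an overall pass flag as attribute `pass`.
#' @examples
#' params <- realize_parameters(default_registry(), "base")
#' cohort <- simulate_cohort(params, "biopsy_all", n = 5000, seed = 1)
#' compare_to_analytic(cohort_summary(cohort),
#'                     evaluate_strategy(params, "biopsy_all"))
#' @export
compare_to_analytic <- function(summary, analytic, z_max = 4) {
  stopifnot(is.data.frame(analytic), nrow(analytic) == 1)
  out <- summary |>
    dplyr::mutate(
      analytic = purrr::map_dbl(.data$quantity, function(q) analytic[[q]]),
      z = dplyr::if_else(
        .data$se > 0,
        (.data$estimate - .data$analytic) / .data$se,
        dplyr::if_else(
          abs(.data$estimate - .data$analytic) <=
            1e-9 * pmax(1, abs(.data$analytic)),
          0, Inf
        )
      ),
      pass = abs(.data$z) <= z_max
    ) |>
    dplyr::select("quantity", empirical = "estimate", "analytic", "se",
                  "z", "pass")
  attr(out, "pass") <- all(out$pass)
  out
}
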