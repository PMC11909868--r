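#' Diagnostic strategies in the model
#'
#' The model compares four ways of handling a patient with suspected IPF
#' whose multidisciplinary work-up remains inconclusive:
#' a non-invasive machine-learning image classifier (`ml_algorithm`), a
#' bronchoscopic genomic classifier (`genomic_classifier`), universal
#' surgical lung biopsy (`biopsy_all`), and universal empiric antifibrotic
#' treatment (`treat_all`).
#'
#' @return Character vector of the four strategy identifiers.
#' @export
strategy_ids <- function() {
  c("ml_algorithm", "genomic_classifier", "biopsy_all", "treat_all")
}

# Coerce a parameter set (named list or data frame of >= 1 rows) to a list
# of aligned numeric vectors, checking every model symbol is present.
as_param_list <- function(params) {
  if (is.data.frame(params)) {
    params <- as.list(params)
  }
  if (!is.list(params)) {
    rlang::abort("`params` must be a data frame or named list.")
  }
  missing <- setdiff(registry_symbols(), names(params))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Parameter set is missing symbol(s): ", paste(missing, collapse = ", ")
    ))
  }
  params[registry_symbols()]
}

# The full pathway enumeration for one strategy, with all numeric fields
# vectorized over parameter draws. This single function defines the tree:
# the cohort expectation, the pathway audit table, and the microsimulation
# all consume its output.
#
# Tree structure (test arms): a positive first-line result sends the patient
# straight to treatment (true or false positive). An inconclusive result is
# referred to surgical biopsy with probability p_referral; biopsied patients
# risk procedural death, and survivors are classified by the biopsy's own
# sensitivity/specificity. Unreferred inconclusive patients are untreated
# (false/true negative) unless the scenario treats them empirically.
# biopsy_all sends everyone to biopsy; treat_all treats everyone.
strategy_pathways <- function(p, strategy, scenario = cea_scenario()) {
  pi <- p$prevalence
  d <- p$p_biopsy_death
  sb <- p$sens_biopsy
  cb <- p$spec_biopsy
  r <- p$p_referral
  pit <- scenario$p_inconclusive_treat

  path <- function(disease, test_result, biopsied, died, state, prob) {
    list(
      disease = disease, test_result = test_result, biopsied = biopsied,
      died_biopsy = died, state = state, probability = prob
    )
  }

  if (strategy %in% c("ml_algorithm", "genomic_classifier")) {
    if (strategy == "ml_algorithm") {
      s <- p$sens_algo; cs <- p$spec_algo
    } else {
      s <- p$sens_gc; cs <- p$spec_gc
    }
    pw <- list(
      # positive first-line result: treated immediately, no biopsy
      path("ipf", "positive", FALSE, FALSE, "TP", pi * s),
      path("no_ipf", "positive", FALSE, FALSE, "FP", (1 - pi) * (1 - cs)),
      # inconclusive, not referred
      path("ipf", "inconclusive", FALSE, FALSE, "FN",
           pi * (1 - s) * (1 - r) * (1 - pit)),
      path("no_ipf", "inconclusive", FALSE, FALSE, "TN",
           (1 - pi) * cs * (1 - r) * (1 - pit)),
      path("ipf", "inconclusive", FALSE, FALSE, "TP",
           pi * (1 - s) * (1 - r) * pit),
      path("no_ipf", "inconclusive", FALSE, FALSE, "FP",
           (1 - pi) * cs * (1 - r) * pit),
      # inconclusive, referred to surgical biopsy
      path("ipf", "inconclusive", TRUE, TRUE, "death",
           pi * (1 - s) * r * d),
      path("no_ipf", "inconclusive", TRUE, TRUE, "death",
           (1 - pi) * cs * r * d),
      path("ipf", "inconclusive", TRUE, FALSE, "TP",
           pi * (1 - s) * r * (1 - d) * sb),
      path("ipf", "inconclusive", TRUE, FALSE, "FN",
           pi * (1 - s) * r * (1 - d) * (1 - sb)),
      path("no_ipf", "inconclusive", TRUE, FALSE, "TN",
           (1 - pi) * cs * r * (1 - d) * cb),
      path("no_ipf", "inconclusive", TRUE, FALSE, "FP",
           (1 - pi) * cs * r * (1 - d) * (1 - cb))
    )
  } else if (strategy == "biopsy_all") {
    pw <- list(
      path("ipf", "none", TRUE, TRUE, "death", pi * d),
      path("no_ipf", "none", TRUE, TRUE, "death", (1 - pi) * d),
      path("ipf", "none", TRUE, FALSE, "TP", pi * (1 - d) * sb),
      path("ipf", "none", TRUE, FALSE, "FN", pi * (1 - d) * (1 - sb)),
      path("no_ipf", "none", TRUE, FALSE, "TN", (1 - pi) * (1 - d) * cb),
      path("no_ipf", "none", TRUE, FALSE, "FP", (1 - pi) * (1 - d) * (1 - cb))
    )
  } else if (strategy == "treat_all") {
    one <- rep(1, length(pi))
    pw <- list(
      path("ipf", "none", FALSE, FALSE, "TP", pi * one),
      path("no_ipf", "none", FALSE, FALSE, "FP", (1 - pi) * one)
    )
  } else {
    rlang::abort(paste0("Unknown strategy: ", strategy))
  }
  pw
}

# Arm-level supplemental diagnostic fee and false-positive benefit
# probability. The genomic classifier is costed as the classifier assay
# plus the bronchoscopy required to collect its specimen, charged to every
# patient in the arm.
arm_settings <- function(p, strategy, scenario) {
  fee <- switch(strategy,
    ml_algorithm = p$c_algo,
    genomic_classifier = p$c_classifier + p$c_bronch,
    biopsy_all = 0,
    treat_all = 0
  )
  fp_benefit <- if (strategy == "treat_all") {
    scenario$p_fp_benefit_treatall %||% p$p_fp_benefit_treatall
  } else {
    scenario$p_fp_benefit_test %||% p$p_fp_benefit_test
  }
  list(fee = fee, fp_benefit = fp_benefit)
}

# Payoffs attached to one pathway. Biopsy deaths accrue the arm fee and the
# biopsy cost (both incurred before death) but no downstream care and zero
# QALYs. Treated states (TP/FP) pay lifetime treatment cost and the expected
# treatment-complication disutility; negative states pay lifetime symptom
# management. Biopsy survivors carry the procedure disutility. A
# false-positive pathway's QALY payoff is upgraded toward the true-positive
# payoff with the arm's false-positive-benefit probability (0 by default).
pathway_payoffs <- function(pw, p, strategy, scenario = cea_scenario()) {
  arm <- arm_settings(p, strategy, scenario)
  treated <- pw$state %in% c("TP", "FP")
  died <- pw$died_biopsy
  q_state <- switch(pw$state,
    TP = p$q_tp,
    FP = p$q_fp + arm$fp_benefit * (p$q_tp - p$q_fp),
    TN = p$q_tn,
    FN = p$q_fn,
    death = 0
  )
  cost_diag <- arm$fee + 0 * p$c_slb
  cost_biopsy <- if (pw$biopsied) p$c_slb else 0 * p$c_slb
  cost_treatment <- if (treated && !died) {
    p$c_treat * scenario$treat_cost_multiplier
  } else {
    0 * p$c_treat
  }
  cost_symptom <- if (pw$state %in% c("TN", "FN")) p$c_symptom else 0 * p$c_symptom
  qaly <- if (died) {
    0 * p$q_tp
  } else {
    q_state -
      (if (pw$biopsied) p$u_biopsy else 0) -
      (if (treated) p$u_complication else 0)
  }
  list(
    cost_diag = cost_diag, cost_biopsy = cost_biopsy,
    cost_treatment = cost_treatment, cost_symptom = cost_symptom,
    cost = cost_diag + cost_biopsy + cost_treatment + cost_symptom,
    qaly = qaly
  )
}

#' Enumerate the terminal pathways of one strategy
#'
#' Expands the decision tree for a single parameter set into its terminal
#' pathways, with branch labels, the pathway probability (product of branch
#' probabilities), and the cost and QALY payoffs, split into the four cost
#' components (supplemental diagnostics, biopsy, treatment, symptom
#' management).
#'
#' @param params A one-row data frame or named list supplying every model
#'   symbol, e.g. from [realize_parameters()].
#' @param strategy One of [strategy_ids()].
#' @param scenario A [cea_scenario()].
#'
#' @return A tibble with one row per terminal pathway; probabilities sum
#'   to 1 within each strategy.
#' @examples
#' realize_parameters(default_registry(), "base") |>
#'   enumerate_pathways("ml_algorithm")
#' @export
enumerate_pathways <- function(params, strategy, scenario = cea_scenario()) {
  if (!(strategy %in% strategy_ids())) {
    rlang::abort(paste0("Unknown strategy: ", strategy))
  }
  p <- as_param_list(params)
  if (any(lengths(p) != 1L)) {
    rlang::abort("`enumerate_pathways()` takes a single parameter set.")
  }
  pw <- strategy_pathways(p, strategy, scenario)
  purrr::map_dfr(pw, function(path) {
    pay <- pathway_payoffs(path, p, strategy, scenario)
    tibble::tibble(
      strategy = strategy,
      disease = path$disease,
      test_result = path$test_result,
      biopsied = path$biopsied,
      died_biopsy = path$died_biopsy,
      state = path$state,
      probability = path$probability,
      cost_diag = pay$cost_diag,
      cost_biopsy = pay$cost_biopsy,
      cost_treatment = pay$cost_treatment,
      cost_symptom = pay$cost_symptom,
      cost = pay$cost,
      qaly = pay$qaly
    )
  })
}

#' Evaluate a strategy analytically (cohort expectation)
#'
#' Probability-weighted expectation over the strategy's terminal pathways:
#' expected cost (split into supplemental-diagnostic, biopsy, treatment and
#' symptom-management components), expected QALYs, and the terminal-event
#' probabilities. Vectorized over parameter draws: a data frame of `n`
#' parameter sets yields `n` result rows.
#'
#' @param params A data frame of parameter sets (one per row), or a named
#'   list; a `.draw` column, if present, is carried through.
#' @inheritParams enumerate_pathways
#'
#' @return A tibble with columns `strategy`, `total_cost`, `qalys`,
#'   `cost_supplemental`, `cost_biopsy`, `cost_symptom`, `cost_treatment`,
#'   `p_tp`, `p_fp`, `p_tn`, `p_fn`, `p_biopsy_death`, `p_biopsied`.
#' @examples
#' realize_parameters(default_registry(), "mean") |>
#'   evaluate_strategy("biopsy_all")
#' @export
evaluate_strategy <- function(params, strategy, scenario = cea_scenario()) {
  if (!(strategy %in% strategy_ids())) {
    rlang::abort(paste0("Unknown strategy: ", strategy))
  }
  draw <- if (is.data.frame(params) && ".draw" %in% names(params)) {
    params$.draw
  } else {
    NULL
  }
  p <- as_param_list(params)
  m <- max(lengths(p))
  pw <- strategy_pathways(p, strategy, scenario)

  zero <- numeric(m)
  acc <- list(
    total_cost = zero, qalys = zero,
    cost_supplemental = zero, cost_biopsy = zero,
    cost_symptom = zero, cost_treatment = zero,
    p_tp = zero, p_fp = zero, p_tn = zero, p_fn = zero,
    p_biopsy_death = zero, p_biopsied = zero
  )
  for (path in pw) {
    pay <- pathway_payoffs(path, p, strategy, scenario)
    pr <- path$probability
    acc$total_cost <- acc$total_cost + pr * pay$cost
    acc$qalys <- acc$qalys + pr * pay$qaly
    acc$cost_supplemental <- acc$cost_supplemental + pr * pay$cost_diag
    acc$cost_biopsy <- acc$cost_biopsy + pr * pay$cost_biopsy
    acc$cost_symptom <- acc$cost_symptom + pr * pay$cost_symptom
    acc$cost_treatment <- acc$cost_treatment + pr * pay$cost_treatment
    key <- paste0("p_", tolower(path$state))
    if (path$state == "death") key <- "p_biopsy_death"
    acc[[key]] <- acc[[key]] + pr
    if (path$biopsied) acc$p_biopsied <- acc$p_biopsied + pr
  }
  out <- tibble::as_tibble(acc)
  out <- tibble::add_column(out, strategy = strategy, .before = 1)
  if (!is.null(draw)) out <- tibble::add_column(out, .draw = draw, .before = 1)
  out
}

#' Evaluate all four strategies on one set of parameter draws
#'
#' @inheritParams evaluate_strategy
#' @return A tibble stacking [evaluate_strategy()] results for every
#'   strategy, evaluated on the same parameter sets (common random numbers
#'   across strategies in a PSA).
#' @examples
#' realize_parameters(default_registry(), "base") |> evaluate_all()
#' @export
evaluate_all <- function(params, scenario = cea_scenario()) {
  purrr::map_dfr(
    strategy_ids(),
    function(s) evaluate_strategy(params, s, scenario)
  )
}
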