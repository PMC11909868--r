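#' Model parameter registry
#'
#' The model is driven by a registry of 23 parameters: unit costs,
#' probabilities governing the diagnostic pathways, and lifetime
#' quality-of-life payoffs. Each entry carries a base (deterministic) value,
#' the full range used for one-way sensitivity analysis, and the
#' distribution sampled in probabilistic sensitivity analysis (PSA), or a
#' flag marking it as held fixed across PSA draws.
#'
#' `default_registry()` returns the packaged base-case registry.
#' `as_registry()` validates a user-supplied data frame (for example an
#' edited copy of the default) and returns it with solved distribution shape
#' parameters attached.
#'
#' @details
#' Distribution summaries are stored in `g1`/`g2`, interpreted according to
#' `parameterization`:
#' * `mean_median` (lognormal): `g1` = mean, `g2` = median;
#' * `mean_sd` (beta or normal): `g1` = mean, `g2` = SD;
#' * `shape_pair` (beta): `g1` = alpha, `g2` = beta;
#' * `point` (fixed): `g1` = the value, `g2` ignored.
#'
#' Solved sampling parameters are stored in `p1`/`p2` (lognormal:
#' meanlog/sdlog; beta: alpha/beta; normal: mean/sd; fixed: value/NA).
#'
#' Validation enforces: every required symbol present exactly once;
#' `low <= base <= high`; distributions solvable; beta-distributed rows
#' confined to \[0, 1\]; nonnegative costs and utilities.
#'
#' @param x A data frame with columns `name`, `base`, `low`, `high`,
#'   `family`, `parameterization`, `g1`, `g2`, `psa_fixed` (and optionally
#'   `label`).
#'
#' @return A tibble of class `cea_registry`.
#' @examples
#' reg <- default_registry()
#' reg[reg$name == "sens_biopsy", ]
#' @export
default_registry <- function() {
  row <- function(name, label, base, low, high, family, parameterization,
                  g1, g2 = NA_real_, psa_fixed = FALSE) {
    tibble::tibble(
      name = name, label = label, base = base, low = low, high = high,
      family = family, parameterization = parameterization,
      g1 = g1, g2 = g2, psa_fixed = psa_fixed
    )
  }
  reg <- dplyr::bind_rows(
    # -- costs (2022 US dollars, lifetime where noted) --
    row("c_algo", "Machine-learning algorithm fee", 5000, 500, 10000,
        "lognormal", "mean_median", 5000, 4900),
    row("c_classifier", "Genomic classifier fee", 5793, 500, 10000,
        "lognormal", "mean_median", 5793, 5500),
    row("c_bronch", "Bronchoscopy", 11170, 872, 35039,
        "lognormal", "mean_median", 11170, 5689),
    row("c_slb", "Surgical lung biopsy", 42373, 27048, 57698,
        "lognormal", "mean_median", 42373, 34482),
    row("c_symptom", "Lifetime symptom management", 84073, 10000, 120000,
        "lognormal", "mean_median", 84073, 72000),
    row("c_treat", "Lifetime nintedanib treatment", 711579, 100000, 900000,
        "lognormal", "mean_median", 711579, 575000),
    # -- probabilities --
    row("p_referral", "Inconclusive result referred to biopsy", 0.75, 0, 1,
        "beta", "mean_sd", 0.75, 0.15),
    row("sens_algo", "Algorithm sensitivity", 0.53, 0.41, 0.65,
        "beta", "mean_sd", 0.53, 0.059),
    row("spec_algo", "Algorithm specificity", 0.86, 0.77, 0.93,
        "beta", "mean_sd", 0.86, 0.040),
    row("sens_gc", "Genomic classifier sensitivity", 0.68, 0.55, 0.73,
        "beta", "mean_sd", 0.68, 0.045),
    row("spec_gc", "Genomic classifier specificity", 0.92, 0.81, 0.95,
        "beta", "mean_sd", 0.92, 0.035),
    row("p_biopsy_death", "Biopsy results in death", 0.064, 0.01, 0.17,
        "beta", "mean_sd", 0.064, 0.02),
    row("sens_biopsy", "Biopsy sensitivity", 0.75, 0.5, 1,
        "beta", "shape_pair", 27, 7),
    row("spec_biopsy", "Biopsy specificity", 0.90, 0.8, 1,
        "beta", "mean_sd", 0.9, 0.05),
    row("p_fp_benefit_test", "FP treatment benefit (test/biopsy arms)",
        0, 0, 0.4, "fixed", "point", 0, psa_fixed = TRUE),
    row("p_fp_benefit_treatall", "FP treatment benefit (treat-all arm)",
        0, 0, 0.2, "fixed", "point", 0, psa_fixed = TRUE),
    row("prevalence", "IPF prevalence in work-up population", 0.404, 0.1, 0.6,
        "beta", "shape_pair", 626, 922),
    # -- quality of life (lifetime QALYs and decrements) --
    row("u_biopsy", "Disutility of surgical lung biopsy", 0.013, 0, 0.026,
        "fixed", "point", 0.013, psa_fixed = TRUE),
    row("q_fn", "Lifetime QALYs, false negative", 3.78, 2.78, 4.78,
        "lognormal", "mean_median", 3.78, 3.7),
    row("q_fp", "Lifetime QALYs, false positive", 3.7, 2.7, 4.7,
        "lognormal", "mean_median", 3.7, 3.6),
    row("q_tn", "Lifetime QALYs, true negative", 3.78, 2.85, 4.85,
        "lognormal", "mean_median", 3.78, 3.7),
    row("q_tp", "Lifetime QALYs, true positive", 4.15, 3.15, 5.15,
        "lognormal", "mean_median", 4.15, 4.05),
    row("u_complication", "Treatment-complication disutility", 0.03, 0, 0.1,
        "normal", "mean_sd", 0.03, 0.01)
  )
  as_registry(reg)
}

# Canonical symbol set the decision model consumes.
registry_symbols <- function() {
  c(
    "c_algo", "c_classifier", "c_bronch", "c_slb", "c_symptom", "c_treat",
    "p_referral", "sens_algo", "spec_algo", "sens_gc", "spec_gc",
    "p_biopsy_death", "sens_biopsy", "spec_biopsy",
    "p_fp_benefit_test", "p_fp_benefit_treatall", "prevalence",
    "u_biopsy", "q_fn", "q_fp", "q_tn", "q_tp", "u_complication"
  )
}

# Which symbols are probabilities (validated to [0,1]).
probability_symbols <- function() {
  c(
    "p_referral", "sens_algo", "spec_algo", "sens_gc", "spec_gc",
    "p_biopsy_death", "sens_biopsy", "spec_biopsy",
    "p_fp_benefit_test", "p_fp_benefit_treatall", "prevalence"
  )
}

#' @rdname default_registry
#' @export
as_registry <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("name", "base", "low", "high", "family", "parameterization",
              "g1", "g2", "psa_fixed")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "Registry is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!("label" %in% names(x))) x$label <- x$name

  absent <- setdiff(registry_symbols(), x$name)
  if (length(absent) > 0) {
    rlang::abort(paste0(
      "Registry is missing parameter(s): ", paste(absent, collapse = ", ")
    ))
  }
  dup <- x$name[duplicated(x$name)]
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "Duplicated registry entries: ", paste(unique(dup), collapse = ", ")
    ))
  }
  unknown <- setdiff(x$name, registry_symbols())
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "Unknown registry entries: ", paste(unknown, collapse = ", ")
    ))
  }

  bad_range <- x$name[!(x$low <= x$base & x$base <= x$high)]
  if (length(bad_range) > 0) {
    rlang::abort(paste0(
      "Base value outside sensitivity range for: ",
      paste(bad_range, collapse = ", ")
    ))
  }

  # Solve sampling parameters row by row so errors name the offending row.
  solved <- purrr::pmap(
    list(x$name, x$family, x$parameterization, x$g1, x$g2),
    function(name, family, parameterization, g1, g2) {
      res <- tryCatch(
        solve_row(family, parameterization, g1, g2),
        error = function(e) {
          rlang::abort(paste0(
            "Registry row '", name, "': ", conditionMessage(e)
          ))
        }
      )
      res
    }
  )
  x$p1 <- purrr::map_dbl(solved, 1)
  x$p2 <- purrr::map_dbl(solved, 2)

  probs <- x[x$name %in% probability_symbols(), ]
  bad_prob <- probs$name[probs$low < 0 | probs$high > 1]
  if (length(bad_prob) > 0) {
    rlang::abort(paste0(
      "Probability range outside [0, 1] for: ",
      paste(bad_prob, collapse = ", ")
    ))
  }
  nonneg <- x[!(x$name %in% probability_symbols()), ]
  bad_neg <- nonneg$name[nonneg$low < 0 | nonneg$base < 0]
  if (length(bad_neg) > 0) {
    rlang::abort(paste0(
      "Costs and QALY payoffs must be nonnegative: ",
      paste(bad_neg, collapse = ", ")
    ))
  }

  # Stable canonical ordering: sampling is column-wise in this order, so a
  # fixed order keeps seeded draws reproducible across registry sources.
  x <- x[match(registry_symbols(), x$name), ]
  class(x) <- c("cea_registry", class(tibble::tibble()))
  x
}

solve_row <- function(family, parameterization, g1, g2) {
  if (family == "lognormal") {
    if (parameterization != "mean_median") {
      rlang::abort("lognormal rows use the 'mean_median' parameterization.")
    }
    s <- solve_lognormal(g1, g2)
    return(c(s$meanlog, s$sdlog))
  }
  if (family == "beta") {
    if (parameterization == "mean_sd") {
      s <- solve_beta_mean_sd(g1, g2)
      return(c(s$alpha, s$beta))
    }
    if (parameterization == "shape_pair") {
      if (!is.finite(g1) || !is.finite(g2) || g1 <= 0 || g2 <= 0) {
        rlang::abort("beta shape parameters must be positive.")
      }
      return(c(g1, g2))
    }
    rlang::abort("beta rows use 'mean_sd' or 'shape_pair'.")
  }
  if (family == "normal") {
    if (parameterization != "mean_sd") {
      rlang::abort("normal rows use the 'mean_sd' parameterization.")
    }
    if (!is.finite(g2) || g2 <= 0) rlang::abort("normal SD must be positive.")
    return(c(g1, g2))
  }
  if (family == "fixed") {
    return(c(g1, NA_real_))
  }
  rlang::abort(paste0("unknown family '", family, "'."))
}

#' Realize a concrete parameter set from the registry
#'
#' Collapses the registry to one assignment of every model symbol:
#' either the deterministic base-case point (`mode = "base"`) or the point
#' given by each PSA distribution's analytic mean (`mode = "mean"`). The
#' two differ wherever a distribution's mean is not its base value — e.g.
#' biopsy sensitivity has base 0.75 but a Beta(27, 7) distribution whose
#' mean is 27/34, and prevalence Beta(626, 922) has mean 626/1548. Because
#' the decision tree is multilinear in independent parameters, PSA averages
#' converge to the `mode = "mean"` point, which is why deterministic
#' replication of PSA-based results uses it.
#'
#' @param registry A `cea_registry`, typically [default_registry()].
#' @param mode `"base"` or `"mean"`.
#'
#' @return A one-row tibble with one column per model parameter.
#' @examples
#' realize_parameters(default_registry(), "mean")$sens_biopsy # 27/34
#' @export
realize_parameters <- function(registry, mode = c("base", "mean")) {
  registry <- as_registry(registry)
  mode <- rlang::arg_match(mode)
  vals <- if (mode == "base") {
    registry$base
  } else {
    ifelse(
      registry$psa_fixed,
      registry$base,
      purrr::pmap_dbl(
        list(registry$family, registry$p1, registry$p2),
        distribution_mean
      )
    )
  }
  out <- tibble::as_tibble(as.list(stats::setNames(vals, registry$name)))
  out
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter sets from the registry's PSA
#' distributions. Rows flagged `psa_fixed` are held at their base value in
#' every draw. Draws are independent across parameters (no correlation
#' structure is specified for these inputs) and are reproducible for a given
#' seed: sampling proceeds column-wise in the registry's canonical order.
#'
#' @inheritParams realize_parameters
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#'
#' @return An `n`-row tibble, one column per model parameter, plus a
#'   `.draw` index column.
#' @examples
#' draws <- sample_parameters(default_registry(), n = 5, seed = 1)
#' @export
sample_parameters <- function(registry, n, seed = NULL) {
  registry <- as_registry(registry)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  draw_cols <- function() {
    cols <- purrr::pmap(
      list(registry$name, registry$family, registry$p1, registry$p2,
           registry$psa_fixed, registry$base),
      function(name, family, p1, p2, psa_fixed, base) {
        if (psa_fixed) rep(base, n) else sample_distribution(family, p1, p2, n)
      }
    )
    stats::setNames(cols, registry$name)
  }
  cols <- if (is.null(seed)) {
    draw_cols()
  } else {
    withr::with_seed(as.integer(seed), draw_cols())
  }
  out <- tibble::as_tibble(cols)
  out$.draw <- seq_len(n)
  out
}
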