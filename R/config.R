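#' Read and write registry configuration files
#'
#' The registry round-trips through a plain JSON file, one object per
#' parameter, so a base case can be archived alongside results or edited
#' outside R. `read_registry()` validates on load and raises an error
#' naming the offending row when a file is inconsistent.
#'
#' @param path File path. `read_registry()` with no arguments loads the
#'   packaged base-case configuration, which is identical to
#'   [default_registry()].
#' @param registry A `cea_registry`.
#'
#' @return `read_registry()` returns a `cea_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_registry(default_registry(), path)
#' identical(read_registry(path), default_registry())
#' @export
read_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_registry.json",
                        package = "ipfcea", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    rlang::abort(paste0("Registry file not found: ", path))
  }
  x <- jsonlite::fromJSON(path)
  as_registry(tibble::as_tibble(x))
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  registry <- as_registry(registry)
  out <- registry[, c("name", "label", "base", "low", "high",
                      "family", "parameterization", "g1", "g2", "psa_fixed")]
  jsonlite::write_json(out, path, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Scenario settings
#'
#' Scenario knobs that modify the model without being PSA parameters:
#' a multiplier on lifetime treatment cost (generic-entry scenarios), the
#' probability that a patient with an inconclusive first-line result is
#' treated empirically without biopsy, and optional overrides for the
#' probability that a false-positive patient nevertheless derives full
#' treatment benefit (by arm family).
#'
#' @param treat_cost_multiplier Multiplier on lifetime treatment cost
#'   (default 1; 0.75 and 0.5 correspond to 25% and 50% price reductions).
#' @param p_inconclusive_treat Probability that an inconclusive, unreferred
#'   patient is treated without biopsy (default 0).
#' @param p_fp_benefit_test Override for the false-positive benefit
#'   probability in the algorithm/classifier/biopsy arms (default: registry
#'   value, 0 in the base case).
#' @param p_fp_benefit_treatall Override for the treat-all arm.
#'
#' @return A list of class `cea_scenario`.
#' @examples
#' cea_scenario(treat_cost_multiplier = 0.5)
#' @export
cea_scenario <- function(treat_cost_multiplier = 1,
                         p_inconclusive_treat = 0,
                         p_fp_benefit_test = NULL,
                         p_fp_benefit_treatall = NULL) {
  chk01 <- function(x, what) {
    if (!is.null(x) && (!is.numeric(x) || x < 0 || x > 1)) {
      rlang::abort(paste0("`", what, "` must be in [0, 1]."))
    }
  }
  if (!is.numeric(treat_cost_multiplier) || treat_cost_multiplier < 0) {
    rlang::abort("`treat_cost_multiplier` must be nonnegative.")
  }
  chk01(p_inconclusive_treat, "p_inconclusive_treat")
  chk01(p_fp_benefit_test, "p_fp_benefit_test")
  chk01(p_fp_benefit_treatall, "p_fp_benefit_treatall")
  structure(
    list(
      treat_cost_multiplier = treat_cost_multiplier,
      p_inconclusive_treat = p_inconclusive_treat,
      p_fp_benefit_test = p_fp_benefit_test,
      p_fp_benefit_treatall = p_fp_benefit_treatall
    ),
    class = "cea_scenario"
  )
}
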