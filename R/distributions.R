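#' Solve a lognormal distribution from its mean and median
#'
#' Health-economic model inputs are often published as a (mean, median) pair
#' for right-skewed cost and QALY quantities. A two-parameter lognormal is
#' uniquely determined by that pair: the median fixes the location of the
#' underlying normal and the mean/median ratio fixes its spread.
#'
#' With `meanlog = log(median)` and `sdlog = sqrt(2 * log(mean / median))`,
#' the lognormal has exactly the requested median (`exp(meanlog)`) and mean
#' (`exp(meanlog + sdlog^2 / 2)`).
#'
#' @param mean Target arithmetic mean (> 0). Must be >= `median`, since a
#'   lognormal mean never falls below its median.
#' @param median Target median (> 0).
#'
#' @return A tibble with one row and columns `meanlog` and `sdlog`, suitable
#'   for [stats::rlnorm()].
#' @examples
#' solve_lognormal(42373, 34482)
#' @export
solve_lognormal <- function(mean, median) {
  if (!is.numeric(mean) || !is.numeric(median) ||
      length(mean) != 1L || length(median) != 1L) {
    rlang::abort("`mean` and `median` must be single numbers.")
  }
  if (!is.finite(mean) || !is.finite(median) || mean <= 0 || median <= 0) {
    rlang::abort("`mean` and `median` must be positive and finite.")
  }
  if (mean < median) {
    rlang::abort(
      "A lognormal distribution has mean >= median; got mean < median."
    )
  }
  tibble::tibble(
    meanlog = log(median),
    sdlog = sqrt(2 * log(mean / median))
  )
}

#' Solve a beta distribution from its mean and standard deviation
#'
#' Method-of-moments inversion: with
#' `nu = mean * (1 - mean) / sd^2 - 1`, the shape pair
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` reproduces the requested
#' mean and standard deviation exactly. A beta distribution with the stated
#' mean exists only when `sd^2 < mean * (1 - mean)`.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param sd Target standard deviation (> 0).
#'
#' @return A tibble with one row and columns `alpha` and `beta`, suitable for
#'   [stats::rbeta()].
#' @examples
#' solve_beta_mean_sd(0.75, 0.15)
#' @export
solve_beta_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) ||
      length(mean) != 1L || length(sd) != 1L) {
    rlang::abort("`mean` and `sd` must be single numbers.")
  }
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    rlang::abort("`mean` must lie strictly between 0 and 1.")
  }
  if (!is.finite(sd) || sd <= 0) {
    rlang::abort("`sd` must be positive and finite.")
  }
  if (sd^2 >= mean * (1 - mean)) {
    rlang::abort(
      "No beta distribution exists: need sd^2 < mean * (1 - mean)."
    )
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  tibble::tibble(alpha = mean * nu, beta = (1 - mean) * nu)
}

# Sample n values from one registry row's PSA distribution.
# Normal decrements are truncated at zero by resampling: a negative
# quality-of-life decrement is meaningless and the mass below zero at
# 3 SD is negligible.
sample_distribution <- function(family, p1, p2, n) {
  switch(family,
    lognormal = stats::rlnorm(n, meanlog = p1, sdlog = p2),
    beta = stats::rbeta(n, shape1 = p1, shape2 = p2),
    normal = {
      x <- stats::rnorm(n, mean = p1, sd = p2)
      while (any(bad <- x < 0)) {
        x[bad] <- stats::rnorm(sum(bad), mean = p1, sd = p2)
      }
      x
    },
    fixed = rep(p1, n),
    rlang::abort(paste0("Unknown distribution family: ", family))
  )
}

# Analytic mean of one registry row's distribution (untruncated for normal;
# the truncation at 0 sits ~3 SD out and shifts the mean negligibly).
distribution_mean <- function(family, p1, p2) {
  switch(family,
    lognormal = exp(p1 + p2^2 / 2),
    beta = p1 / (p1 + p2),
    normal = p1,
    fixed = p1,
    rlang::abort(paste0("Unknown distribution family: ", family))
  )
}
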