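#' Efficiency frontier with strong and extended dominance
#'
#' Sorts strategies by mean cost, removes strongly dominated strategies
#' (another strategy costs no more and yields no fewer QALYs, at least one
#' strictly), then iteratively removes extendedly dominated strategies
#' (whose ICER against their frontier predecessor exceeds the next frontier
#' strategy's ICER against them) until the ICERs along the frontier
#' strictly increase. Incremental costs, QALYs and ICERs are reported along
#' the surviving chain, from unrounded inputs.
#'
#' Exact cost/QALY ties keep the earlier-listed strategy on the frontier
#' and mark the other dominated, so the result is deterministic.
#'
#' @param points A data frame with columns `strategy` (or `name`), `cost`
#'   and `qaly`, one row per strategy (e.g. PSA means from [tidy.cea_psa()]).
#'
#' @return A tibble of class `cea_frontier`, sorted by cost, with `status`
#'   in `on_frontier` / `dominated` / `extendedly_dominated` and columns
#'   `incremental_cost`, `incremental_qaly`, `icer` (NA off the frontier and
#'   for the cheapest frontier strategy).
#' @examples
#' icer_frontier(tibble::tibble(
#'   strategy = c("A", "B", "C"),
#'   cost = c(0, 10, 5), qaly = c(0, 1, 0.2)
#' ))
#' @export
icer_frontier <- function(points) {
  points <- tibble::as_tibble(points)
  if ("name" %in% names(points) && !("strategy" %in% names(points))) {
    points <- dplyr::rename(points, strategy = "name")
  }
  needed <- c("strategy", "cost", "qaly")
  if (!all(needed %in% names(points))) {
    rlang::abort("`points` needs columns strategy (or name), cost, qaly.")
  }
  if (nrow(points) == 0) rlang::abort("`points` must have at least one row.")

  pts <- points[needed]
  pts$.input_order <- seq_len(nrow(pts))
  # sort by cost; among equal costs, higher QALY first, then input order
  pts <- pts[order(pts$cost, -pts$qaly, pts$.input_order), ]
  n <- nrow(pts)
  status <- rep("on_frontier", n)

  # strong dominance (ties resolved by input order)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- pts$cost[i]; qi <- pts$qaly[i]
      cj <- pts$cost[j]; qj <- pts$qaly[j]
      dominates <- (cj <= ci && qj >= qi && (cj < ci || qj > qi)) ||
        (cj == ci && qj == qi && pts$.input_order[j] < pts$.input_order[i])
      if (dominates && status[j] != "dominated") {
        status[i] <- "dominated"
      }
    }
  }

  # extended dominance: drop interior points until ICERs strictly increase
  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) < 3) break
    icers <- diff(pts$cost[idx]) / diff(pts$qaly[idx])
    bad <- which(utils::head(icers, -1) >= utils::tail(icers, -1))
    if (length(bad) == 0) break
    status[idx[bad[1] + 1]] <- "extendedly_dominated"
  }

  idx <- which(status == "on_frontier")
  inc_cost <- inc_qaly <- icer <- rep(NA_real_, n)
  if (length(idx) > 1) {
    inc_cost[idx[-1]] <- diff(pts$cost[idx])
    inc_qaly[idx[-1]] <- diff(pts$qaly[idx])
    icer[idx[-1]] <- inc_cost[idx[-1]] / inc_qaly[idx[-1]]
  }

  out <- tibble::tibble(
    strategy = pts$strategy,
    cost = pts$cost,
    qaly = pts$qaly,
    status = status,
    incremental_cost = inc_cost,
    incremental_qaly = inc_qaly,
    icer = icer
  )
  class(out) <- c("cea_frontier", class(out))
  out
}

#' Net monetary benefit
#'
#' `nmb = wtp * qaly - cost`: the health benefit of a strategy converted to
#' dollars at a willingness-to-pay per QALY, minus its cost. Negative NMB
#' means the strategy's opportunity costs outweigh its benefits at that
#' threshold. Vectorized in all three arguments.
#'
#' @param cost Total cost in dollars.
#' @param qaly QALYs.
#' @param wtp Willingness-to-pay threshold in dollars per QALY (>= 0).
#' @return Net monetary benefit in dollars.
#' @examples
#' nmb(345680, 3.63, 1e5)
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) rlang::abort("`wtp` must be nonnegative.")
  wtp * qaly - cost
}

#' Default willingness-to-pay thresholds
#'
#' The five thresholds at which sensitivity analyses are reported:
#' $50,000 to $250,000 per QALY in $50,000 steps. There is no single
#' accepted US threshold, so results are shown across this range.
#' @return Numeric vector of thresholds ($/QALY).
#' @export
wtp_thresholds <- function() {
  c(50000, 100000, 150000, 200000, 250000)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' cost-effective: the fraction of PSA draws in which it attains the
#' maximum net monetary benefit. Exact ties within a draw split the draw's
#' mass equally among the tied strategies, so probabilities sum to one at
#' every threshold.
#'
#' @param psa A `cea_psa` object from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values ($/QALY).
#' @return A tibble of class `cea_ceac` with columns `wtp`, `strategy`,
#'   `probability`.
#' @examples
#' psa <- run_psa(default_registry(), n = 200, seed = 1)
#' ceac(psa, wtp_grid = seq(0, 3e5, by = 1e5))
#' @export
ceac <- function(psa, wtp_grid = seq(0, 250000, by = 10000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0) rlang::abort("`wtp_grid` must be nonempty.")
  res <- psa$results
  strategies <- strategy_ids()
  k <- length(strategies)
  cost <- matrix(NA_real_, nrow = psa$n, ncol = k)
  qaly <- matrix(NA_real_, nrow = psa$n, ncol = k)
  for (j in seq_len(k)) {
    rows <- res[res$strategy == strategies[j], ]
    rows <- rows[order(rows$.draw), ]
    cost[, j] <- rows$total_cost
    qaly[, j] <- rows$qalys
  }
  out <- purrr::map_dfr(wtp_grid, function(w) {
    b <- w * qaly - cost
    best <- apply(b, 1, max)
    win <- b == best
    weights <- win / rowSums(win)
    tibble::tibble(
      wtp = w,
      strategy = strategies,
      probability = colMeans(weights)
    )
  })
  class(out) <- c("cea_ceac", class(out))
  out
}
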