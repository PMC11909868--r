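# Shared generators and independent oracles used across tests.

# A random but valid parameter set (all probabilities in [0,1], positive
# costs and payoffs). Used for property-style tests of the tree algebra.
random_param_set <- function() {
  rp <- function(lo = 0, hi = 1) stats::runif(1, lo, hi)
  tibble::tibble(
    c_algo = rp(500, 10000),
    c_classifier = rp(500, 10000),
    c_bronch = rp(872, 35039),
    c_slb = rp(27048, 57698),
    c_symptom = rp(10000, 120000),
    c_treat = rp(100000, 900000),
    p_referral = rp(),
    sens_algo = rp(),
    spec_algo = rp(),
    sens_gc = rp(),
    spec_gc = rp(),
    p_biopsy_death = rp(0, 0.3),
    sens_biopsy = rp(),
    spec_biopsy = rp(),
    p_fp_benefit_test = 0,
    p_fp_benefit_treatall = 0,
    prevalence = rp(0.05, 0.95),
    u_biopsy = rp(0, 0.026),
    q_fn = rp(2, 5),
    q_fp = rp(2, 5),
    q_tn = rp(2, 5),
    q_tp = rp(2, 6),
    u_complication = rp(0, 0.1)
  )
}

# A registry whose every row is a point mass at its base value: a PSA over
# it must return the base case on every draw.
degenerate_registry <- function() {
  reg <- default_registry()
  reg$family <- "fixed"
  reg$parameterization <- "point"
  reg$g1 <- reg$base
  reg$g2 <- NA_real_
  as_registry(reg)
}

# Independent frontier oracle: a strategy lies on the efficiency frontier
# iff it is the unique net-monetary-benefit maximizer for some
# willingness-to-pay. Candidate thresholds are all pairwise incremental
# ratios; testing the midpoints between consecutive candidates (plus the
# extremes) covers every linear ordering the points can induce.
frontier_oracle_members <- function(points) {
  cost <- points$cost
  qaly <- points$qaly
  n <- length(cost)
  lambdas <- c(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dq <- qaly[i] - qaly[j]
      if (dq != 0) {
        l <- (cost[i] - cost[j]) / dq
        if (is.finite(l) && l > 0) lambdas <- c(lambdas, l)
      }
    }
  }
  lambdas <- sort(unique(lambdas))
  probes <- c(
    lambdas[1] / 2,
    (utils::head(lambdas, -1) + utils::tail(lambdas, -1)) / 2,
    utils::tail(lambdas, 1) * 2 + 1
  )
  probes <- unique(c(0, probes))
  on <- rep(FALSE, n)
  for (l in probes) {
    b <- l * qaly - cost
    winners <- which(b == max(b))
    if (length(winners) == 1) on[winners] <- TRUE
  }
  sort(points$strategy[on])
}

# Random cost/QALY instances for frontier property tests; continuous draws
# make exact ties almost surely absent.
random_frontier_points <- function(n_points) {
  tibble::tibble(
    strategy = paste0("s", seq_len(n_points)),
    cost = stats::runif(n_points, 0, 100),
    qaly = stats::runif(n_points, 0, 10)
  )
}
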