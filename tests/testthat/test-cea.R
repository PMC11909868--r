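test_that("strong and extended dominance are detected on worked examples", {
  # interior point with a higher ICER than its successor is extendedly
  # dominated: A(0,0) -> C(5,0.2) has ICER 25, C -> B(10,1) has 6.25
  fr <- icer_frontier(tibble::tibble(
    strategy = c("A", "C", "B"), cost = c(0, 5, 10), qaly = c(0, 0.2, 1)
  ))
  expect_equal(fr$status[fr$strategy == "C"], "extendedly_dominated")
  expect_equal(fr$status[fr$strategy %in% c("A", "B")],
               rep("on_frontier", 2))
  expect_equal(fr$icer[fr$strategy == "B"], 10)

  fr2 <- icer_frontier(tibble::tibble(
    strategy = c("X", "Y"), cost = c(10, 5), qaly = c(1, 2)
  ))
  expect_equal(fr2$status[fr2$strategy == "X"], "dominated")
  expect_equal(fr2$status[fr2$strategy == "Y"], "on_frontier")
  expect_true(all(is.na(fr2$icer)))

  expect_error(icer_frontier(tibble::tibble(strategy = character(),
                                            cost = numeric(),
                                            qaly = numeric())),
               "at least one row")
})

test_that("exact ties keep the earlier-listed strategy on the frontier", {
  fr <- icer_frontier(tibble::tibble(
    strategy = c("first", "twin"), cost = c(5, 5), qaly = c(1, 1)
  ))
  expect_equal(fr$status[fr$strategy == "first"], "on_frontier")
  expect_equal(fr$status[fr$strategy == "twin"], "dominated")
})

test_that("frontier ICERs strictly increase and the frontier is idempotent", {
  withr::with_seed(31, {
    for (k in 1:100) {
      pts <- random_frontier_points(sample(2:6, 1))
      fr <- icer_frontier(pts)
      icers <- fr$icer[!is.na(fr$icer)]
      if (length(icers) > 1) {
        expect_true(all(diff(icers) > 0))
      }
      # dropping an off-frontier point never changes the frontier
      off <- fr$strategy[fr$status != "on_frontier"]
      if (length(off) > 0) {
        fr2 <- icer_frontier(pts[pts$strategy != off[1], ])
        on1 <- fr[fr$status == "on_frontier",
                  c("strategy", "cost", "qaly", "icer")]
        on2 <- fr2[fr2$status == "on_frontier",
                   c("strategy", "cost", "qaly", "icer")]
        expect_equal(on1, on2)
      }
    }
  })
})

test_that("frontier membership agrees with the NMB-maximizer oracle", {
  withr::with_seed(32, {
    for (k in 1:100) {
      pts <- random_frontier_points(sample(2:6, 1))
      fr <- icer_frontier(pts)
      expect_equal(
        sort(fr$strategy[fr$status == "on_frontier"]),
        frontier_oracle_members(pts)
      )
    }
  })
})

test_that("net monetary benefit is the linear valuation it claims to be", {
  expect_equal(nmb(345680, 3.63, 100000), 17320)
  expect_equal(nmb(0, 0, 123456), 0)
  expect_lt(nmb(500000, 1, 100000), 0)
  # linearity in all three arguments
  expect_equal(nmb(2 * 100, 2 * 0.5, 300), 2 * nmb(100, 0.5, 300))
  expect_equal(nmb(100 + 7, 0.5, 300), nmb(100, 0.5, 300) - 7)
  expect_equal(nmb(100, 0.5 + 0.1, 300), nmb(100, 0.5, 300) + 0.1 * 300)
  expect_error(nmb(1, 1, -5), "nonnegative")
})

test_that("acceptability curves are proper probabilities with the right limits", {
  psa <- run_psa(default_registry(), n = 400, seed = 23)
  grid <- seq(0, 2e6, length.out = 21)
  cc <- ceac(psa, grid)
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-12)

  # at wtp = 0 the mass sits on the per-draw cheapest strategy
  cc0 <- ceac(psa, 0)
  cheapest <- psa$results |>
    dplyr::group_by(.draw) |>
    dplyr::summarise(w = strategy[which.min(total_cost)])
  freq <- table(factor(cheapest$w, levels = strategy_ids())) / psa$n
  expect_equal(cc0$probability, as.numeric(freq))

  # as wtp grows the per-draw QALY maximizer takes all the mass
  cc_inf <- ceac(psa, 1e12)
  best_q <- psa$results |>
    dplyr::group_by(.draw) |>
    dplyr::summarise(w = strategy[which.max(qalys)])
  freq_q <- table(factor(best_q$w, levels = strategy_ids())) / psa$n
  expect_equal(cc_inf$probability, as.numeric(freq_q))
})

test_that("exact NMB ties split a draw's mass equally", {
  psa <- run_psa(default_registry(), n = 50, seed = 29)
  # make two strategies identical on every draw
  res <- psa$results
  twin <- res[res$strategy == "biopsy_all", ]
  res[res$strategy == "treat_all",
      setdiff(names(res), c("strategy", ".draw"))] <-
    twin[, setdiff(names(twin), c("strategy", ".draw"))]
  psa$results <- res
  cc <- ceac(psa, 0)
  expect_equal(cc$probability[cc$strategy == "biopsy_all"],
               cc$probability[cc$strategy == "treat_all"])
  expect_equal(sum(cc$probability), 1, tolerance = 1e-12)
})
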