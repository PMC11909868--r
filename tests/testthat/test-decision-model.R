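test_that("pathway probabilities sum to one for every strategy and draw", {
  withr::with_seed(21, {
    for (k in 1:50) {
      params <- random_param_set()
      for (s in strategy_ids()) {
        pw <- enumerate_pathways(params, s)
        expect_equal(sum(pw$probability), 1, tolerance = 1e-12)
        expect_true(all(pw$probability >= 0 & pw$probability <= 1))
      }
    }
  })
})

test_that("cost components are nonnegative and sum to pathway and total cost", {
  withr::with_seed(22, {
    for (k in 1:20) {
      params <- random_param_set()
      res <- evaluate_all(params)
      expect_equal(
        res$cost_supplemental + res$cost_biopsy + res$cost_symptom +
          res$cost_treatment,
        res$total_cost,
        tolerance = 1e-9
      )
      expect_true(all(res$cost_supplemental >= 0 & res$cost_biopsy >= 0 &
                        res$cost_symptom >= 0 & res$cost_treatment >= 0))
      expect_equal(
        res$p_tp + res$p_fp + res$p_tn + res$p_fn + res$p_biopsy_death,
        rep(1, 4),
        tolerance = 1e-12
      )
      expect_true(all(res$p_biopsied >= res$p_biopsy_death))
    }
  })
})

test_that("evaluate_strategy equals the probability-weighted pathway sums", {
  params <- realize_parameters(default_registry(), "mean")
  for (s in strategy_ids()) {
    pw <- enumerate_pathways(params, s)
    res <- evaluate_strategy(params, s)
    expect_equal(res$total_cost, sum(pw$probability * pw$cost))
    expect_equal(res$qalys, sum(pw$probability * pw$qaly))
    expect_equal(res$cost_biopsy, sum(pw$probability * pw$cost_biopsy))
    expect_equal(res$p_fp, sum(pw$probability[pw$state == "FP"]))
  }
})

test_that("treat-all has no diagnostics and pays exactly the treatment cost", {
  pb <- realize_parameters(default_registry(), "base")
  res <- evaluate_strategy(pb, "treat_all")
  expect_equal(res$total_cost, 711579)
  expect_equal(res$cost_supplemental, 0)
  expect_equal(res$cost_biopsy, 0)
  expect_equal(res$cost_symptom, 0)
  expect_equal(res$p_biopsied, 0)
  expect_equal(res$p_biopsy_death, 0)
  expect_equal(res$p_tp, pb$prevalence)
})

test_that("degenerate branches collapse as expected", {
  params <- random_param_set()
  params$prevalence <- 1
  params$sens_algo <- 1
  pw <- enumerate_pathways(params, "ml_algorithm")
  pw <- pw[pw$probability > 0, ]
  expect_equal(nrow(pw), 1)
  expect_equal(pw$state, "TP")
  expect_equal(pw$probability, 1)

  params2 <- random_param_set()
  params2$prevalence <- 0
  res <- evaluate_strategy(params2, "ml_algorithm")
  expect_equal(res$p_tp, 0)
  expect_equal(res$p_fn, 0)
})

test_that("distribution-mean event probabilities match hand expansion", {
  pm <- realize_parameters(default_registry(), "mean")
  ba <- evaluate_strategy(pm, "biopsy_all")
  # everyone biopsied; survivors classified by the biopsy's accuracy
  treated_hand <- (1 - pm$p_biopsy_death) *
    (pm$prevalence * pm$sens_biopsy +
       (1 - pm$prevalence) * (1 - pm$spec_biopsy))
  expect_equal(ba$p_tp + ba$p_fp, treated_hand, tolerance = 1e-12)
  expect_equal(ba$p_tp + ba$p_fp, 0.356, tolerance = 5e-3)
  expect_equal(ba$p_biopsied, 1)

  ml <- evaluate_strategy(pm, "ml_algorithm")
  biopsied_hand <- pm$p_referral *
    (1 - pm$prevalence * pm$sens_algo -
       (1 - pm$prevalence) * (1 - pm$spec_algo))
  expect_equal(ml$p_biopsied, biopsied_hand, tolerance = 1e-12)
  expect_equal(ml$p_biopsied, 0.527, tolerance = 5e-3)
})

test_that("biopsy-all QALYs at the distribution-mean point reproduce 3.63", {
  pm <- realize_parameters(default_registry(), "mean")
  expect_equal(evaluate_strategy(pm, "biopsy_all")$qalys, 3.63,
               tolerance = 0.01)
})

test_that("costs and QALYs respond monotonically to their drivers", {
  base <- realize_parameters(default_registry(), "base")
  bump <- function(p, name, delta) {
    p[[name]] <- p[[name]] + delta
    p
  }
  for (s in strategy_ids()) {
    r0 <- evaluate_strategy(base, s)
    for (cost_name in c("c_slb", "c_treat", "c_symptom", "c_algo",
                        "c_classifier", "c_bronch")) {
      r1 <- evaluate_strategy(bump(base, cost_name, 1000), s)
      expect_gte(r1$total_cost, r0$total_cost)
    }
    r_ub <- evaluate_strategy(bump(base, "u_biopsy", 0.01), s)
    expect_lte(r_ub$qalys, r0$qalys)
    r_uc <- evaluate_strategy(bump(base, "u_complication", 0.01), s)
    expect_lte(r_uc$qalys, r0$qalys)
  }
  # biopsy deaths scale with referral in the test arms, never in treat-all
  hi <- bump(base, "p_referral", 0.2)
  for (s in c("ml_algorithm", "genomic_classifier")) {
    expect_gt(evaluate_strategy(hi, s)$p_biopsy_death,
              evaluate_strategy(base, s)$p_biopsy_death)
  }
  expect_equal(evaluate_strategy(hi, "treat_all")$p_biopsy_death, 0)
})

test_that("scenario knobs act exactly as specified", {
  base <- realize_parameters(default_registry(), "base")
  r1 <- evaluate_all(base, cea_scenario(treat_cost_multiplier = 1))
  r05 <- evaluate_all(base, cea_scenario(treat_cost_multiplier = 0.5))
  expect_equal(r05$cost_treatment, r1$cost_treatment / 2)
  expect_equal(r05$cost_biopsy, r1$cost_biopsy)
  expect_identical(r1, evaluate_all(base))

  # everyone with an inconclusive result treated, nobody referred
  p <- base
  p$p_referral <- 0
  res <- evaluate_strategy(p, "ml_algorithm",
                           cea_scenario(p_inconclusive_treat = 1))
  expect_equal(res$p_tn, 0)
  expect_equal(res$p_fn, 0)
  expect_equal(res$p_tp + res$p_fp, 1)
})

test_that("false-positive treatment benefit upgrades FP QALYs toward TP", {
  base <- realize_parameters(default_registry(), "base")
  pw0 <- enumerate_pathways(base, "treat_all")
  pw1 <- enumerate_pathways(base, "treat_all",
                            cea_scenario(p_fp_benefit_treatall = 1))
  fp0 <- pw0[pw0$state == "FP", ]
  fp1 <- pw1[pw1$state == "FP", ]
  # full benefit: FP payoff equals the TP payoff (still treated, still
  # paying treatment cost and complication decrement)
  expect_equal(fp1$qaly, pw1$qaly[pw1$state == "TP"])
  expect_equal(fp1$cost, fp0$cost)
  expect_gt(fp1$qaly, fp0$qaly)
  # the test-arm knob does not leak into treat-all and vice versa
  pw2 <- enumerate_pathways(base, "treat_all",
                            cea_scenario(p_fp_benefit_test = 1))
  expect_equal(pw2$qaly[pw2$state == "FP"], fp0$qaly)
})

test_that("unknown strategies are rejected", {
  base <- realize_parameters(default_registry(), "base")
  expect_error(enumerate_pathways(base, "watchful_waiting"), "Unknown strategy")
  expect_error(evaluate_strategy(base, "none"), "Unknown strategy")
})
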