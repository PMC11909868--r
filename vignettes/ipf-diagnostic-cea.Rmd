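---
title: "Methods: a decision-analytic model of IPF diagnostic strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic model of IPF diagnostic strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `ipfcea`: its structure,
its parameterization, the statistical machinery around it, and the
numerical and design choices a user should know before trusting (or
extending) its output. It states no empirical result that the package's
code does not itself compute.

## 1. Decision problem

The population is adults with suspected idiopathic pulmonary fibrosis
(IPF) whose multidisciplinary work-up remains inconclusive. Four
strategies are compared:

1. **`ml_algorithm`** — a machine-learning classifier applied to
   already-acquired CT imaging; conclusive results are acted on
   directly, inconclusive results may be referred to surgical lung
   biopsy (SLB).
2. **`genomic_classifier`** — a transbronchial genomic classifier;
   same downstream structure, but every tested patient incurs both the
   classifier fee and a bronchoscopy cost.
3. **`biopsy_all`** — every patient goes straight to SLB.
4. **`treat_all`** — every patient receives antifibrotic treatment
   with no further testing.

The perspective is the US health sector; payoffs are lifetime expected
costs (US dollars) and quality-adjusted life years (QALYs) attached to
each terminal diagnostic state, inherited from the source cost model.
There is no explicit time dimension in this package: the decision tree
is single-pass and the lifetime payoffs arrive pre-discounted as scalar
state values. No Markov structure or discounting is performed here.

## 2. Tree structure

Let π be the IPF prevalence. For a test arm with sensitivity $s$ and
specificity $c$:

- A diseased patient tests **positive** with probability $s$ and is
  treated (true positive, TP).
- A non-diseased patient tests positive with probability $1-c$ and is
  treated (false positive, FP).
- All other results are **inconclusive**. Inconclusive patients are
  referred to SLB with probability $r$ (`p_referral`); unreferred
  patients go untreated (FN if diseased, TN if not).
- Biopsied patients die with probability $d$ (`p_biopsy_death`),
  accruing the costs incurred up to and including the biopsy and zero
  QALYs. Survivors are classified by the biopsy's own sensitivity
  $s_b$ and specificity $c_b$.

`biopsy_all` is the same tree with the first-line test removed;
`treat_all` has two terminal states (TP for diseased, FP for not).

Terminal payoffs:

- TP: arm fee (+ SLB cost if biopsied) + lifetime treatment cost;
  QALYs `q_tp` minus the biopsy disutility `u_biopsy` (if biopsied and
  survived) minus the treatment-complication disutility
  `u_complication` (applied to **all** treated patients, TP and FP).
- FP: as TP on the cost side, but QALYs start from `q_fp`. A fraction
  of false positives (`p_fp_benefit_test` in the test arms,
  `p_fp_benefit_treatall` under treat-all; both 0 by default) is
  "upgraded" to the TP utility: `q_fp + benefit · (q_tp − q_fp)`.
- TN/FN: arm fee (+ SLB if biopsied) + symptom-management cost
  `c_symptom`; QALYs `q_tn` or `q_fn`, minus `u_biopsy` if biopsied.
- Biopsy death: fee + `c_slb`; zero QALYs.

`enumerate_pathways()` exposes every pathway with its probability,
cost, and QALY payoff; `evaluate_strategy()` returns the
probability-weighted cohort expectations plus a cost decomposition
(supplemental test fees, biopsy, symptom management, treatment) and
terminal-state probabilities. The patient-level simulator
(`simulate_cohort()`) traverses the identical pathway/payoff tables, so
its per-patient costs and QALYs are drawn from exactly the analytic
payoff set; `compare_to_analytic()` z-tests the Monte Carlo means
against the cohort expectations (zero-variance quantities are compared
within a relative 1e-9, since floating-point pathway sums differ from
their exact values at the 1e-16 level).

## 3. Parameters

`default_registry()` holds the 23 model inputs as a tibble, one row per
parameter: base-case value, deterministic low/high range, and a PSA
distribution. Units: costs in US dollars, probabilities and test
characteristics on [0, 1], QALY payoffs in quality-adjusted life years,
disutilities in QALYs subtracted.

| name | meaning | base |
|---|---|---|
| `c_algo` | ML classifier fee | 1,000 |
| `c_classifier` | genomic classifier fee | 5,793 |
| `c_bronch` | bronchoscopy | 11,170 |
| `c_slb` | surgical lung biopsy | 42,180 |
| `c_symptom` | lifetime symptom management | 64,169 |
| `c_treat` | lifetime antifibrotic treatment | 626,924 |
| `p_referral` | referral of inconclusive results to SLB | 0.50 |
| `sens_algo` / `spec_algo` | ML classifier accuracy | 0.74 / 0.92 |
| `sens_gc` / `spec_gc` | genomic classifier accuracy | 0.70 / 0.88 |
| `p_biopsy_death` | SLB mortality | 0.064 |
| `sens_biopsy` / `spec_biopsy` | SLB accuracy | 0.75 / 0.96 |
| `p_fp_benefit_test` / `p_fp_benefit_treatall` | FP utility upgrade share | 0 |
| `prevalence` | IPF prevalence | 0.404 |
| `u_biopsy` | biopsy disutility | 0.013 |
| `q_fn` / `q_fp` / `q_tn` / `q_tp` | terminal-state QALYs | 2.10 / 3.13 / 5.89 / 4.01 |
| `u_complication` | treatment-complication disutility | 0.009 |

Two evaluation points exist and differ:

- `realize_parameters(reg, "base")` — the deterministic base-case
  column; used by the sensitivity module.
- `realize_parameters(reg, "mean")` — each parameter at its PSA
  **distribution mean** (e.g. `sens_biopsy` is Beta(27, 7) with mean
  0.794, not its base 0.75). Because the tree's expectations are
  multilinear in the independently sampled inputs, the PSA means of
  costs and QALYs converge to this point's values, so it is the right
  deterministic companion to a PSA summary.

### Distribution solvers

- **Lognormal from (mean, median)** (`solve_lognormal`): the median
  gives `meanlog = log(median)`, then
  `sdlog = sqrt(2 · log(mean/median))`; requires mean > median.
- **Beta from (mean, SD)** (`solve_beta_mean_sd`): method of moments,
  `ν = mean(1−mean)/sd² − 1`, `α = mean·ν`, `β = (1−mean)·ν`; requires
  `sd² < mean(1−mean)`.
- **Normal, truncated at zero**: sampled by resampling negative draws,
  used for inputs quoted with a symmetric SE that must stay
  nonnegative. The resampling shifts the realized mean slightly above
  the nominal one when the SD is large relative to the mean; for the
  registry's rows the truncation mass is negligible.
- Registry validation (`as_registry()`) fails loudly, naming the row,
  when a distribution is unsolvable or a base/low/high value leaves
  its support.

All parameters are sampled **independently** — no correlation structure
is imposed, matching the source analysis; joint uncertainty in, say, a
test's sensitivity and specificity is therefore ignored.

## 4. Probabilistic analysis

`run_psa(registry, n, seed)` draws `n` parameter sets and evaluates all
four strategies on **common random numbers** (the same draw feeds every
strategy), which tightens incremental comparisons. The reproducibility
contract is the pair (seed, n): the same pair yields bit-identical
draws, because sampling is done column-wise in canonical registry order
under a single `withr::with_seed`. Changing `n` reshuffles everything;
there are no per-draw RNG substreams.

`tidy()` on the PSA reports means with **95% confidence intervals of
the mean** (normal approximation, `mean ± 1.96·sd/√n`) — these are
Monte Carlo precision statements about the expected value, *not*
percentile intervals of the per-draw distribution, which under the
lognormal cost inputs would be an order of magnitude wider.

`icer_frontier()` sorts strategies by cost, removes strongly dominated
points (more costly, no more effective; exact ties keep the
earlier-listed strategy), then iteratively removes extendedly dominated
interior points (a point whose incremental ICER is at least its
successor's). The result carries incremental costs, QALYs, and ICERs
along the frontier; the unit tests verify it against a brute-force
net-monetary-benefit argmax oracle on random instances.

`ceac(psa, wtp_grid)` computes, per willingness-to-pay value, the share
of draws on which each strategy maximizes `nmb = wtp·qalys − cost`;
exact ties split a draw's mass equally.

## 5. Deterministic sensitivity analyses

All deterministic analyses hold other parameters at the **base**
column.

- `one_way_sweep()` traces a metric (total cost, diagnostic-only cost,
  QALYs, or NMB) over a grid for one parameter, all strategies at once.
- `tornado()` evaluates each parameter at its registry low/high and
  ranks by span.
- `threshold_search()` bisects one parameter for the point where a
  given strategy becomes/ceases to be the NMB-optimal choice, to a
  relative tolerance of 1e-6 on the parameter; if the optimality
  indicator does not change sign over the registry range it returns
  `found = FALSE` rather than erroring.
- `run_scenarios()` reruns the PSA under structural variants
  (`cea_scenario()`: treatment-cost multiplier, treating a share of
  unreferred inconclusive patients, FP-benefit overrides) with the same
  seed, so scenario deltas are not confounded by sampling noise.

On the willingness-to-pay for threshold statements: the acceptability
analysis evaluates λ ∈ {50,000, …, 250,000} per QALY
(`wtp_thresholds()`). The treatment-cost threshold at which treat-all
becomes NMB-optimal moves with λ; the package's documented headline
threshold (~$177,000) is the one at λ = $250,000/QALY, the top of that
set, and the qualitative result — a finite treatment-cost threshold
below which treat-all is optimal — holds across the set.

## 6. What the microsimulation is, and is not

`simulate_cohort()` is a verification oracle, not a richer model: it
simulates independent patients through the same tree with the same
scalar payoffs, so its means converge to the analytic cohort values at
the canonical 1/√n rate. It does not add patient heterogeneity,
time-to-event structure, real-world test operating points, or any
feature absent from the cohort model. The test suite runs it at
200,000 patients per check (|z| ≤ 4 against analytic values) and a
convergence test across increasing n.

## 7. Problem sizes and numerical notes

- PSA: 10,000 draws (the analysis size used throughout the package's
  examples and tests) runs in well under a second; the microsimulation
  checks simulate 200,000 patients per strategy.
- Frontier tie-breaks: equal-cost/equal-QALY points keep the first in
  input order; ICERs on the returned frontier are strictly increasing.
- `ceac` tie handling and the 1e-9 zero-variance comparison in
  `compare_to_analytic()` are described above.
- Monetary quantities are kept in double precision throughout; nothing
  is rounded until printing.

## 8. Limitations

- Lifetime payoffs are exogenous state values; survival, disease
  progression, and discounting are not modelled here.
- Parameter independence in the PSA ignores sensitivity–specificity
  and cost–utility correlations.
- The referral probability applies one common value to all
  inconclusive results regardless of arm or disease status.
- Results are conditional on the packaged registry; users studying
  other settings should replace rows via `read_registry()` /
  `write_registry()` and re-validate with `as_registry()`.
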