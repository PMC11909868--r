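# ipfcea

Decision-analytic cost-effectiveness model of diagnostic strategies for
idiopathic pulmonary fibrosis (IPF), for health-economics analysts and
methodologists who want a fully scriptable, reproducible version of this
class of analysis in R.

IPF is expensive to diagnose and to treat. Patients whose multidisciplinary
work-up stays inconclusive face a choice among a non-invasive
machine-learning image classifier, a bronchoscopic genomic classifier,
going straight to surgical lung biopsy (the gold standard, with procedural
mortality risk), or empiric antifibrotic treatment for everyone. `ipfcea`
evaluates a decision tree over these four strategies from the US health
sector perspective with lifetime cost and QALY payoffs.

## The model

Each patient has IPF with prevalence π. In the test arms, a first-line
test with sensitivity *s* and specificity *c* either labels the patient
positive (treated immediately) or inconclusive; inconclusive results are
referred to surgical lung biopsy with probability *r*. Biopsied patients
die with probability *d*; survivors are classified by the biopsy's own
sensitivity/specificity (s_b, c_b). Unreferred inconclusive patients go
untreated. Terminal states are TP/FP (treated: lifetime nintedanib cost,
treatment-complication disutility), TN/FN (symptom management), and
biopsy death (costs incurred up to the biopsy, zero QALYs).

Cost-effectiveness is summarized the standard way:

- **ICER** between adjacent strategies on the efficiency frontier,
  ΔC/ΔE, after removing strongly and extendedly dominated strategies;
- **NMB(λ) = λ·E − C** at willingness-to-pay λ per QALY;
- **CEAC**: the probability, across probabilistic-sensitivity-analysis
  (PSA) draws, that each strategy maximizes NMB at a given λ.

PSA draws every uncertain input from its distribution (lognormals
parameterized by mean/median, betas by mean/SD or shape pair) for 10,000
draws and evaluates the tree analytically per draw. A patient-level
microsimulation of the same tree is included as a brute-force check on
the cohort algebra.

## Worked example

```r
library(ipfcea)
library(dplyr)

psa <- run_psa(default_registry(), n = 10000, seed = 1)
cea_table(psa) |> select(strategy, cost, qalys, icer, status)
#>   strategy             cost qalys    icer     status
#> 1 biopsy_all         342272.  3.62      NA  on_frontier
#> 2 ml_algorithm       381693.  3.74  329607. on_frontier
#> 3 genomic_classifier 389185.  3.76  420764. on_frontier
#> 4 treat_all          704978.  3.85 3447168. on_frontier
```

Biopsy-all is cheapest but yields the fewest QALYs (biopsy deaths and
missed cases). The machine-learning arm buys 0.12 extra QALYs at about
$330,000 each; the genomic classifier and treat-all follow at much higher
ICERs — all four lie on the frontier, none is dominated. Diagnostic-only
costs tell the opposite story:

```r
cost_breakdown(psa) |> select(strategy, diagnostic, supplemental, biopsy)
#>   strategy           diagnostic supplemental biopsy
#> 1 biopsy_all              42180            0  42180
#> 2 ml_algorithm            27182         4996  22186
#> 3 genomic_classifier      38500        17089  21411
#> 4 treat_all                   0            0      0
```

The algorithm cuts diagnostic spending by ~$15,000 per patient versus
universal biopsy, because 47% of its results are conclusive and skip the
$42,000 biopsy. At a $250,000/QALY threshold the acceptability curve still
favours biopsy-all:

```r
ceac(psa, wtp_grid = 250000)
#>      wtp strategy           probability
#> 1 250000 ml_algorithm             0.234
#> 2 250000 genomic_classifier       0.215
#> 3 250000 biopsy_all               0.425
#> 4 250000 treat_all                0.126
```

Deterministic analyses (`one_way_sweep()`, `tornado()`,
`threshold_search()`, `run_scenarios()`) and plots
(`autoplot()` on any result object) round out the toolkit; see the
package vignette for the model's assumptions and parameterization.

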