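# webrds

Tools for running and analysing **web-based respondent-driven sampling
(WebRDS)** surveys of hidden populations — groups such as homecare workers,
for whom no sampling frame exists and recruitment must travel through the
population's own social network.

In an RDS survey, researcher-chosen *seeds* complete the survey and receive a
personal invitation link (a *coupon*) with a fixed number of uses — three is
the classic design. Each recruit becomes a recruiter in turn, and the chain
of token redemptions records who invited whom. Because better-connected
people are more likely to be reached, raw sample proportions are biased; the
**RDS-II (Volz–Heckathorn) estimator** corrects this by weighting each
respondent inversely to their self-reported network degree $d_i$:

$$\hat p_A \;=\; \frac{\sum_{i \in A} 1/d_i}{\sum_{i \in S} 1/d_i}$$

for category $A$ within the usable sample $S$. This is asymptotically
unbiased under the with-replacement random-walk model of RDS.

The package is aimed at study teams running a WebRDS in the field (coupon
ledger, duplicate screening, monitoring reports) and at analysts
(estimation, uncertainty, diagnostics):

* **Coupon engine** — an auditable token ledger: issuance with use budgets,
  redemption receipts, administrative extra-use grants, two-step duplicate
  detection (contact match, then answer-fingerprint match) with
  first-response-wins resolution, and a conservation invariant
  (grants − redemptions = remaining uses) checked at any time.
* **Recruitment forest** — reconstruction of the recruiter→recruit forest
  from token linkage, wave assignment, performance summaries (out-degree
  histogram, chain lengths, largest tree), and edge-list CSV / GraphML / DOT
  export. `reference_forest()` builds a deterministic 337-respondent,
  13-tree benchmark forest reproducing the published recruitment summary of
  a nationwide WebRDS survey of homecare workers.
* **Estimators** — RDS-II point estimates with exclusion accounting,
  Salganik-style **chain-bootstrap** percentile confidence intervals,
  **recruitment homophily** (observed vs expected same-category
  recruiter–recruit pairs), convergence and per-seed **bottleneck** series,
  and descriptives for the finite-population/reciprocity diagnostic
  questions.
* **Simulator** — synthetic assortative populations (per-category negative
  binomial degrees; graph mode with degree-preserving rewiring to an
  assortativity target, or the with-replacement markov mode of RDS theory)
  and a coupon-limited referral process whose every enrollment passes
  through the coupon engine, so simulated data satisfy all ledger
  invariants by construction.
* **IO / CLI** — CSV dialects mirroring a LimeSurvey token/response export,
  YAML simulation configs, a JSON+Markdown monitoring report, and a
  `webrds` command-line tool (`simulate`, `estimate`, `homophily`,
  `diagnose`, `metrics`, `report`, `fixture`, `validate`).

## Worked example

```r
library(webrds)

# the deterministic benchmark forest
m <- recruitment_metrics(reference_forest())
print(m)
#> Recruitment performance
#>   respondents: 337 (13 seeds; 324 after seed removal)
#>   recruited >=1: 48.1%   >=2: 30.6%   exactly 3: 17.5%
#>   chain length (waves): median 4, range 1-10
#>   largest tree: 123 nodes (36.5%)
#>   out-degree histogram:  0:175  1:59  2:44  3:59

# simulate a study and estimate a 30%-prevalence trait
pc  <- population_config(2000,
         traits = list(trait = list(labels = c("a", "b"),
                                    prevalence = c(0.3, 0.7))),
         degree_mu = c(a = 8, b = 4))          # group a is twice as connected
pop <- generate_population(pc, rng_seed = 1, mode = "markov")
sim <- simulate_recruitment(pop, sim_config(n_seeds = 8, mode = "markov",
                                            max_sample = 500, rng_seed = 42))
f   <- sim_forest(sim)
est <- chain_bootstrap_ci(responses(sim), f, "trait",
                          replicates = 500, seed = 7)
print(est)
#> RDS-II estimate of 'trait' (n used = 492, excluded = 8)
#>   a              0.287  [0.241, 0.344]
#>   b              0.713  [0.656, 0.759]
```

Group `a` makes up ~44% of the *sample* (its members have twice the mean
degree, so the random walk over-reaches them), yet the inverse-degree
estimate lands near the true 30% with a bootstrap interval that covers it.
The 8 excluded responses are the seeds, left out of estimation by default.

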