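---
title: "WebRDS methods: coupon ledger, RDS-II estimation and recruitment diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WebRDS methods: coupon ledger, RDS-II estimation and recruitment diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webrds)
```

## The sampling design

Respondent-driven sampling (RDS) reaches populations without a sampling
frame by letting the survey travel through the population's own contact
network. Researcher-chosen **seeds** complete the survey and receive a
personal invitation credential (**coupon**, here a unique web token) with a
fixed use budget — three in the classic design this package defaults to.
Every recruit redeems a use of their recruiter's token, completes the
survey, and receives a fresh full-budget token of their own. Recruitment
thus forms a forest of trees rooted at the seeds, with the **wave** of a
respondent equal to their distance from the seed.

Two design facts drive everything downstream:

* the sample is *not* a simple random sample — inclusion probability grows
  with network degree under the random-walk model of RDS; and
* observations are *dependent* along recruitment chains, so i.i.d.
  variance formulas understate uncertainty.

The coupon ledger (`rds_study`) is the package's field-side component: a
mutable, append-only-audited record of token issuance, redemption and
administrative correction. Operations validate before mutating, so a failed
call leaves the ledger untouched, and the conservation identity

> lifetime grants − successful redemptions = Σ remaining uses

is exposed by `coupon_conservation()` and asserted property-style in the
test suite over randomized event replays, including the field-error
scenarios (exhausted links revived by one extra use, duplicate responses
resolved by keeping the first and refunding consumed uses).

Redemption and survey completion are deliberately a two-phase protocol: a
redemption returns a one-shot *receipt* that `complete_response()`
consumes. This prevents one redemption spawning two respondents, and lets
abandoned redemptions (link clicked, survey never finished) be expired and
refunded after a configurable TTL (`expire_receipts()`; off by default —
studies usually reconcile these by manual grants, and the ledger keeps the
audit trail either way).

## Duplicate screening

Online surveys invite multiple participation. The screen is two-step, run
on the response table:

1. **Contact match** — identical normalized non-empty contact strings
   (lower-cased, punctuation and whitespace stripped; empty never matches).
2. **Answer fingerprint** — identical values on every fingerprint variable
   *and* on both network-size answers. The fingerprint set is
   caller-supplied and defaults to all attribute columns; exact equality is
   used, as fuzzy matching would need a similarity threshold that no field
   evidence pins down.

Clusters from the two steps are merged when they overlap (the relation's
transitive closure, verified in tests against a brute-force pairwise
oracle), and resolution keeps the earliest submission — the first response
is the official one — returning removed rows for the audit log and the
recruiter tokens they consumed as refund candidates.

## The RDS-II estimator

For a categorical attribute with categories $A$, the estimator is

$$\hat p_A = \frac{\sum_{i \in A} 1/d_i}{\sum_{i \in S} 1/d_i},$$

with $d_i$ the respondent's self-reported count of target-population
members they could contact right now (the second of the two network-size
questions; the first, broader count is kept for sensitivity reruns via
`degree_var = "degree_known"`). Under with-replacement random-walk sampling
the stationary inclusion probability is proportional to degree, and the
inverse-degree weights undo exactly that.

Exclusion rules, surfaced in `n_excluded` with a reason tally rather than
silently applied:

* **seeds** (default) — purposively chosen, not network-sampled; the Table-2
  convention of the study this package's benchmark emulates;
* **zero or missing degree** — $1/d$ undefined; no imputation, as any
  imputed degree would be an untestable guess with direct leverage on the
  weights;
* **missing category**.

Invariants tested: estimates sum to one, are invariant to rescaling all
degrees by a constant, and agree with an independently coded
weighted-proportion oracle to $10^{-12}$ on small tables.

## Chain-bootstrap confidence intervals

Resampling must respect chain dependence. The package implements the
Salganik-style chain bootstrap: from the observed recruiter→recruit edges,
each category $k$ gets a pool of respondents *recruited by* a member of
$k$. A replicate starts from a uniformly drawn usable respondent and chains
$n$ draws, each taken uniformly with replacement from the pool keyed by the
current respondent's category (uniform over all usable respondents if the
pool is empty); RDS-II is recomputed per replicate and percentile intervals
are reported. Defaults: $B = 1000$, level 0.95, resample size $n$. The
bootstrap is vectorised across replicates, so $B = 500$ at $n = 500$ runs
in well under a second.

Seeds are excluded from estimation but their outgoing edges *do* inform the
transition pools — transitions are about the referral process, not the
estimand. An `exclude_seeds = FALSE` rerun and a seed-edge-free homophily
variant are available for sensitivity.

This bootstrap's exact flavour matters for calibration, which is why the
package carries a Monte-Carlo coverage experiment (below) rather than
assuming nominal coverage.

## Recruitment homophily

With $O$ the number of usable edges whose endpoints share a category and
$n_{rk}$, $n_{ck}$ the per-category edge counts on the recruiter and
recruit side,

$$H = \frac{O}{E^*}, \qquad E^* = \sum_k \frac{n_{rk}\,n_{ck}}{|E|}.$$

$H = 1$ is proportionate mixing (and is *exact*, not approximate, for a
constant attribute); $H = 2$ results from two equal groups recruiting only
their own. The permutation test in the suite shuffles recruit categories
and confirms the null distribution centres at 1.

## Convergence and bottleneck diagnostics

`convergence_series()` recomputes the RDS-II estimate on the first $k$
respondents in submission order for every $k$: a flat tail suggests the
estimate has escaped its seed dependence. Ties in submission time are
broken by participant id for determinism. `bottleneck_series()` computes
the same per seed tree; trajectories that settle at different levels
reveal recruitment trapped in network sub-communities. Prefix estimates
are computed by cumulative weight sums, so the full series costs one pass.

## The simulator

The simulator exists so the entire pipeline — ledger, forest, estimators,
reports — can be exercised end to end without field data, and so estimator
properties can be checked against known truth.

**Population.** Traits are sampled from stated prevalences; degrees are
per-category negative binomial (dispersion 1.5), floored at 1 so everyone
is reachable. No empirical degree distribution is published for
populations like homecare workers, so the default mean of 8 is a
placeholder for a well-connected occupational group and is flagged as such
in the configuration docs.

**Graph mode** (finite population, realistic): a simple configuration-model
graph realises the sampled degree sequence exactly, then degree-preserving
double-edge swaps rewire it until the same-category edge fraction is within
±0.01 of the target $\min(h \cdot \sum_k q_k^2, 1)$, where $q_k$ are
degree-weighted category shares and $h$ is the assortativity knob ($h = 1$:
proportionate mixing). If the bounded swap budget cannot reach the target,
generation fails reporting the achieved level rather than silently
under-delivering. Referral samples unenrolled neighbours without
replacement.

**Markov mode** (the with-replacement regime of RDS theory): no explicit
graph; recruit categories follow the mixing matrix implied by $h$ and the
degree-weighted shares, and degrees are drawn size-biased within category —
precisely the regime in which RDS-II is consistent, which makes it the
clean setting for recovery experiments. Each invitation converts with
`participation_prob` (default 0.6, a plausible conversion for a motivated
population recruited without monetary incentives).

Every simulated enrollment passes through `redeem_token()` /
`complete_response()`, so simulator output satisfies all coupon invariants
by construction — asserted, not assumed, in the integration tests.
Timestamps are synthetic enrollment-ordered increments with jitter, so
convergence series are well defined. Identical seed and configuration give
byte-identical tables.

What the simulator does **not** emulate: differential internet access,
respondent distrust, promotion-driven recruitment bursts, or degree
misreporting beyond an optional multiplicative lognormal noise model (off
by default). Passing tests therefore demonstrate correctness of the
machinery and calibration under the stated model, not robustness to every
field pathology.

## The benchmark forest

`reference_forest()` deterministically builds a 337-node, 13-tree forest
matching a published recruitment summary (out-degree histogram
{0: 175, 1: 59, 2: 44, 3: 59}; per-tree chain lengths with median 4, range
1–10; largest tree 123 nodes). Construction fixes a per-tree plan of
(size, depth, out-degree composition) chosen to satisfy the histogram
identity $59 + 2\cdot44 + 3\cdot59 = 324 = 337 - 13$, builds a spine per
tree to pin its depth, and attaches remaining internal nodes and leaves
shallow-first. The tests validate it with an independent checker that
recomputes every constraint from the raw edge list.

Two conventions were open and were fixed by arithmetic: percentages use the
full 337 (seeds included) as base, because $162/337 = 48.07 \to 48.1$ and
$123/337 = 36.50 \to 36.5$ match the printed values while 324-based figures
do not; and rounding is half-up to one decimal (`round()`'s half-to-even
would give 36.4). "Recruited three" is read as *exactly* three, the
maximum, consistent with the histogram identity.

## Numerical and design choices

* **Percentile bootstrap intervals** (not BCa): the standard choice for RDS
  chain bootstraps; with `replicates = 1` the interval degenerates to the
  single replicate's estimate by definition of the empirical quantile.
* **Tokens** are 12-character URL-safe random strings with uniqueness
  enforced at creation against the ledger's hash index.
* **Tie-breaks**: submission-time ties by participant id; deterministic
  node ordering by participant id throughout.
* **Degenerate inputs**: empty forests refuse summarisation; estimators
  fail with a reason tally when every row is excluded; extinction before
  any non-seed enrollment is a warning (isolated-seed forest), not an
  error, because that is a legitimate field outcome.
* **Report schema**: the monitoring report ships with a JSON schema and a
  small structural validator covering the subset of JSON-Schema the report
  uses (required keys, types, array items).

## Problem sizes in the checks

The calibration experiments use 200 Monte-Carlo runs of $n = 500$
respondents (8 seeds, markov mode) from a population of 2000 profiles with
binary trait prevalence 0.30 and group mean degrees 8 vs 4 — a twofold
degree difference, large enough that the unweighted sample proportion is
visibly biased (it lands near the degree-weighted share
$0.3\cdot8/(0.3\cdot8+0.7\cdot4) \approx 0.46$) while RDS-II recovers 0.30
within ±0.02 on average. Bootstrap coverage uses $B = 500$ per run against
the nominal 95% level. These sizes give Monte-Carlo standard errors
comfortably inside the tolerances being checked and complete in a few
minutes on one CPU.

## Known limitations

* RDS-I, Gile's successive-sampling estimator, model-assisted variance
  estimators and RDS regression are out of scope; the estimator debate for
  web-mode RDS is unsettled and this package implements the inverse-degree
  workhorse only.
* Homophily is a descriptive ratio on observed edges; it is not a test
  statistic with an analytic null (use the permutation approach shown in
  the tests).
* The chain bootstrap conditions on the observed transition structure;
  with very few edges per category its intervals become unstable, and the
  implementation refuses to run with fewer than two usable edges.
* Duplicate detection with a small fingerprint set over-clusters by
  design (exact equality on few variables); review clusters before
  resolving them.
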