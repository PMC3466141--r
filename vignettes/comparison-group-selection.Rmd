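---
title: "Evaluating matched comparison groups: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating matched comparison groups: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchqual)
```

## What the package models

An index cohort (long-term cancer survivors) is compared against two
candidate comparison groups: a peer-nominated group (subjects named by the
survivors themselves) and a listed sample (purchased telephone records
pre-matched on sex and age within ±5 years). The data are *partially
paired*: every comparison subject is linked to one survivor, but a survivor
may have zero, one or two completed peers and zero or one listed match, so
some survivors contribute correlated observations to both comparison groups
and others to only one or neither. All analyses in this package are built
around that structure.

Two questions are kept deliberately separate:

* **Marginal balance.** Are the group-level distributions of a matching
  variable the same? Tested two-sided, per variable.
* **Pair-level match quality.** Within pairs, is the comparison subject
  close to its own survivor? Operationalised as the absolute within-pair
  difference, and tested one-sided: are peer distances stochastically
  smaller (peer matching better) than listed distances?

The canonical counter-example — pairs (1,10), (10,1), (1,10), (10,1), where
the marginals coincide exactly (both means 5.5) while every pair distance
is 9 — is wired into the test suite and the acceptance script; marginal
balance is necessary but nowhere near sufficient for good matching.

## The permutation null for partially paired data

Both tests use the Wilcoxon rank-sum statistic with midranks for ties; no
asymptotic p-values are ever reported, because group sizes per variable can
be small and the observations are correlated through shared survivors. The
null distribution is generated by permutations that respect the dependence:

* an *exchangeability block* is a set of observations whose labels may be
  permuted under the null with the group counts held fixed;
* each survivor contributing to both groups forms a block of two (label
  swap with probability 1/2); a matched set with two peers in a marginal
  test forms a block of three with one index slot;
* all unpaired observations form a single pooled block re-assigned
  uniformly, preserving the observed group counts.

The construction was left open by the data structure itself — several
permutation schemes preserve the null — and the package's choice (within-
block swaps plus count-preserving reassignment of the unpaired pool) was
selected because it holds both the pairing correlation and the group sizes
fixed. It is *validated empirically rather than assumed*: the acceptance
suite simulates 1000 cohorts from a generator in which peer and listed
values share one conditional law given the survivor (the exchangeability
null) and checks that rejection at α = 0.05 stays inside the exact binomial
95% interval; a shift ladder checks that power is monotone in the true
separation of the distance distributions.

### Exact versus Monte Carlo

With $k$ paired survivors and $u$ unpaired observations of which $a$ carry
the first group's label, the permutation space has
$2^k \binom{u}{a}$ arrangements. `method = "auto"` enumerates exhaustively
whenever this is at most `exact_cap` (default 10⁶, roughly a second of
work) and otherwise samples `n_permutations` arrangements. Monte Carlo
p-values use the $(1 + \#\{T^\* \le T\})/(B + 1)$ convention — the observed
arrangement is itself one realisation of the null — which keeps the test
valid (p is never 0) at the price of a bias of at most $1/(B+1)$, and is
why type-I error lands marginally *below* the nominal level.

### Numerical conventions

* Midranks are multiples of 0.5, so statistic comparisons use an absolute
  tolerance of 10⁻⁸; ties with the observed statistic count toward the
  one-sided p (the "≤ observed" convention), which makes the all-tied
  degenerate case return p = 1 rather than something arbitrary.
* Two-sided p-values for the rank-sum statistic are
  $P(|T^* - E_0| \ge |T - E_0|)$ with $E_0$ the exact null expectation
  $\sum_j \frac{a_j}{m_j}\sum_{i \in j} r_i$ over blocks — not the sample
  mean of a Monte Carlo draw — so exact and Monte Carlo modes use the same
  reference point.
* The categorical statistic is the chi-square deviation of the 2×K
  group-by-category table from its margins-fixed expectation. The blocked
  permutations hold both margins fixed, so expectations need computing only
  once; the statistic is its own two-sided measure (upper tail). A single
  pooled category yields p = 1 with a `degenerate` flag instead of an
  error, because downstream reports must not silently drop rows.
* Per-variable analyses are complete-case: a missing value removes that
  subject from that variable's analysis only. Missing values are empty CSV
  cells and are never imputed. Survivors lacking a comparison subject still
  enter marginal tests as unpaired observations, so the index group's
  complete-case N is not eroded by comparison-group attrition.

## Pair distances

Distances are scale-aware, declared per variable in a `varspec`:
continuous → |difference|; ordinal → |rank difference| on the declared
level order (education uses three ranks: less than high school < high
school graduate < post high school — the least assumptive quantification
that still admits a distance); binary/nominal → 0/1 mismatch. Survivors
with two completed peers contribute one peer distance, by default the first
enrolled peer (`peer_rule = "first"`, deterministic: lowest subject
identifier), with `"mean"` (average of the available peers' distances) as
an alternative. A third conceivable rule — using both peers simultaneously
with cluster-level swaps — is not implemented: it changes the
exchangeability blocks of the pair-level test from swaps of two to richer
structures whose null is no longer comparable across variables, for little
practical gain when at most a handful of survivors have two completed
peers.

## The synthetic cohort generator

The generator exists so that every statistical property of the pipeline can
be checked without access to any individual-level study data. It emulates:

* the recruitment funnel: each survivor nominates at least one peer with
  probability 0.61, nominators name a second peer with probability 30/61,
  and each nominee completes with probability 0.483 — yielding on average
  ≈ 91 nominees and ≈ 44 completed peers per 100 survivors; 96% of
  survivors obtain a listed match;
* hard listed-sample constraints: same sex, age within ± the 5-year
  window (uniform over the window), all other listed variables drawn from
  population marginals independently of the survivor;
* peer similarity via *match fidelity*: a peer copies its survivor's value
  perturbed by a per-variable shift and noise SD (continuous) or retained
  with an agreement probability (categorical). Defaults encode a realistic
  peer pattern: 7.5 years younger on average with extra dispersion, only
  partial sex agreement (nominees were not required to be same-sex),
  education well aligned, smoking and drinking slightly heavier.
  `perfect_fidelity()` (all noise zero, agreement one) makes each peer an
  exact copy — the degenerate case the test suite uses as an anchor;
* zero-inflated behaviour variables: 30-day smoking and the three monthly
  alcohol quantities are a point mass at zero plus a truncated normal,
  because population means far below their SDs (smoking days mean ≈ 4,
  SD ≈ 10) are impossible for any unimodal non-negative draw without a
  zero spike;
* survivor marginals: age ≈ N(64.9, 10.09²) truncated at 30, 72% men, 94%
  white, 60% ever-smokers of whom a quarter are current smokers, lifetime
  smoking duration ≈ N(36.6, 15²) for ever-smokers.

`generate_null_cohort()` keeps the pairing/missingness structure but draws
*both* comparison groups from one shared conditional law given the survivor
(symmetric `null_fidelity()`, no hard constraints) — exactly the
exchangeability null of the match-quality test. `generate_shifted_cohort()`
adds a constant to the magnitude of every listed deviation on one
designated variable (default: age), so listed distances are stochastically
larger by exactly that amount; `shift = 0` reproduces the null generator
draw for draw, which pins the power ladder to the type-I anchor.

What the generator does **not** emulate: zip-code geography and telephone
number mechanics; informative (non-random) missingness — masking is MCAR
at a 2% default rate on the education, employment and alcohol items;
within-household correlation of peers; measurement error in self-reported
smoking history. Passing the simulation suite therefore demonstrates
validity under exchangeable-pair correlation and MCAR missingness, not
robustness to informative nonresponse.

All randomness flows from one seed through a locally scoped RNG (the
global `.Random.seed` is saved and restored), so identical config + seed
reproduce cohorts byte-identically and reports serialise deterministically.

## Recruitment accounting

Cost per completed interview is `hourly_rate / completes_per_hour`, total
cost multiplies by completions, yield divides completions by an
arm-specific denominator (usable numbers for list-based arms, nominees for
the peer arm — each arm's funnel has a different natural base). Two
rounding dialects are exposed because published cost tables are not
consistent about cents: truncation (the default; 25/0.60 → 41.66) and
half-up (→ 41.67). Yields similarly take explicit digits and mode, since
44/91 is conventionally quoted as 48.3% (truncated at one decimal) while
whole-percent yields round half-up. The defaults reproduce the quoted
figures; both dials are plain arguments, not hidden state.

## Simulation sizes

The acceptance test suite runs 1000 null cohorts of 100 survivors at 2000
permutations each for the type-I check, a {0, 0.5, 1, 2}·SD shift ladder at
500 replicates and 500 permutations per step for power, 20 enumerable
fixtures at 20 000 permutations for Monte-Carlo-versus-exact agreement, and
200 generator seeds for funnel calibration — sizes at which the binomial
tolerances quoted in the tests are meaningful. The standalone
`scripts/acceptance.R` recomputes the same quantities at 500/200/200
replicates, reporting each `n` alongside the value.

## Known limitations

* The pair-level test compares *distances*, so it is silent about the
  direction of mismatches (a peer 5 years younger and one 5 years older
  are equivalent).
* One variable at a time: no composite or multivariable match-quality
  index, and no multiplicity adjustment across the per-variable p-values —
  the reports are diagnostics, not confirmatory tests.
* With `peer_rule = "first"` the second completed peer is ignored in the
  pair-level analysis (both peers still enter the marginal tests).
* Exact enumeration cost grows as $2^k\binom{u}{a}$; above the cap the
  Monte Carlo error is $O(B^{-1/2})$ and should be budgeted when p-values
  near a decision threshold matter.
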