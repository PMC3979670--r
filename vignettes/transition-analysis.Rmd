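---
title: "Quantifying the structure of dyadic agonistic encounters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structure of dyadic agonistic encounters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoseq)
```

## The analysis problem

ethoseq implements the standard quantitative-ethology pipeline for staged
dyadic encounters between male flesh flies, scored against a closed
16-behavior ethogram. Sessions are 60-minute recordings of two same-age,
socially naive males in a small arena; each animal's stream of behavior is an
alternating sequence of long "background" bouts (walking, standing, grooming,
upside-down — jointly at least 96% of observation time) punctuated by brief
interactive events lasting fractions of a second to a few seconds. The
scientific questions the pipeline answers are: which behavior-to-behavior
transitions occur more often than chance; how that transition structure
reorganizes with age across cohorts tested at 1, 2, 3, 4 and 6 days after
eclosion; and whether encounters show dominance or escalation.

## Transition matrices and the quasi-independence model

For one cohort, every change from one behavior directly to another, pooled
over all individuals, increments a cell of a $k \times k$ count matrix
$n_{ij}$. Self-transitions cannot occur — only *changes* are scored — so the
diagonal is a set of structural zeros, and the appropriate chance model is
*quasi-independence*: $m_{ij} = a_i b_j$ for $i \neq j$, $m_{ii} = 0$, fitted
by iterative proportional scaling (IPF) until fitted row and column sums
match the observed margins (default tolerance $10^{-10}$, uniform positive
initialization; convergence is fast and deterministic at these totals,
and agreement with a brute-force alternating-scaling oracle is checked to
$10^{-9}$ in the tests). Model fit is assessed by the likelihood-ratio
statistic $G = 2\sum_{n_{ij}>0} n_{ij}\ln(n_{ij}/m_{ij})$ with
$df = k^2 - 3k + 1$ ($k^2 - k$ testable cells minus $2k - 1$ fitted
parameters); cells with $n_{ij} = 0$ contribute 0, the $n \ln n \to 0$
limit.

Cell-level departures use Freeman–Tukey deviates,
$z_{ij} = \sqrt{n_{ij}} + \sqrt{n_{ij}+1} - \sqrt{4 m_{ij}+1}$,
approximately standard normal under the fitted model. A transition is
declared significant when its deviate exceeds the simultaneous criterion

$$ c \;=\; \sqrt{\chi^2_{1-\alpha,\,df} \;/\; n_{\text{cells}}}, $$

which partitions the $\alpha$-level model chi-square equally over the
$n_{\text{cells}} = k^2 - k$ testable cells; for the default $k = 16$
analysis, $c \approx 1.008$ at $\alpha = 0.05$. Two design choices deserve
emphasis. First, only *positive* deviates count: the question asked is which
transitions occur *more* often than chance. Second, the criterion value just
above 1 is consistent with kinematic-diagram arrow classes that begin at
deviate 1. On the packaged day-3 matrix this rule reproduces the published
census exactly — 55 significant transitions, of which 18 involve a
high-intensity aggressive behavior (lunge, hold, wrestle, immobilized), 6
connect two high-intensity behaviors, 5 lead into lunge, 5 into wrestle, and
6 distinct non-high-intensity behaviors precede high-intensity ones:

```{r}
fit <- qi_fit(day3_transition_matrix())
fit
classify_hi_involvement(significant_transitions(fit), default_ethogram())[
  c("involving_hi", "hi_to_hi", "distinct_non_hi_precursors")]
```

Borderline cells sit near any defensible criterion (a two-count cell can
clear $c$ when its expected value is small), so alternative significance
rules can shift the census by a cell or two; the packaged criterion is the
one that reproduces the published day-3 pattern cell for cell.

## Cross-cohort comparisons

Age effects on behavioral *frequencies* are tested by likelihood-ratio G
tests of independence on the $k \times a$ tables of first-member (or
second-member) margins by age, $df = (k-1)(a-1)$. Age effects on the
transition *structure* — the three-way behavior 1 × behavior 2 × age
interaction — are tested by comparing per-cohort saturation against the
common-association log-linear model
$\log m_{cij} = r_{ci} + s_{cj} + t_{ij}$ (cohort-specific margins, one
shared association surface, structural-zero diagonal), fitted by three-way
IPF; the likelihood-ratio statistic has $df = (a-1)(k^2-3k+1)$, i.e. 836
for five 16-behavior cohorts. This $df$ follows from the parameter count of
the stated model; the historical analysis of these data reported a different
$df$ (888) from an unstated parameterization, which cannot be reconstructed,
so the printed three-way statistic is not treated as a reproduction target.
Monte-Carlo checks in the test suite confirm the test holds its nominal size
when cohorts are drawn from one common chain.

Persistence of significant transitions across the five ages is summarized by
a partition into: common to all cohorts; appearing from day $d$ onward;
disappearing after day $d$; and everything else. The supplementary matrices
for the day-1/2/4/6 cohorts were published only as word-processor tables
that are not machine-readable, so the cross-cohort partition can be computed
for user-supplied or simulated cohorts but the published cross-cohort counts
cannot be independently recomputed from packaged data; the day-3 matrix is
the fully reproducible anchor.

## Nonparametric ontogeny statistics

Occurrence rates (occurrences · hour⁻¹ · individual⁻¹, computed per
individual) are compared across cohorts with Kruskal–Wallis tests
(tie-corrected) followed by Dunn's multiple comparisons on mean ranks, with
familywise control via the normal approximation adjusted over all
$k(k-1)/2$ pairs — the construction underlying the usual critical-value
tables. Eleven behaviors enter this analysis: the aggressive behaviors
lunge, hold, wrestle and (collapsed) low-intensity aggression; the
interactive non-aggressive avoid, retreat, turn toward and approach; and
jump, stilt, bobbing. Immobilized is excluded because it merely mirrors the
opponent's hold. Time budgets of the four background states are compared as
arcsine-transformed proportions, $p' = \arcsin\sqrt{p}$ in radians (the
classical transform, not the Anscombe variant), with Tukey-type multiple
comparisons using variance $1/(4n)$ with $n$ the cohort's pooled
observation minutes, referred to the studentized range with infinite
degrees of freedom.

Dominance is assessed from the split of a focal behavior between pair
members: per pair, the proportion performed by "individual 1". The observed
histogram of proportions over 11 equal-width bins of $[0,1]$ (boundary
values to the lower bin; df = 10) is compared against the expected
histogram accumulated from each pair's Binomial($n_i$, ½) mass — the null
of no dominant individual. The retreat analysis admits every pair with at
least one event; the hold + lunge analysis requires at least two. With
heterogeneous $n_i$ the binomial reference is discrete and lumpy; the
chi-square approximation is adequate at the pooled study size (54 pairs)
but anti-conservative for single 11-pair cohorts, which is why the
calibration tests pool cohorts exactly as the original design did.
Escalation is tested per cohort by Kruskal–Wallis across five consecutive
10-min intervals (the first and last 5 minutes of each hour are discarded)
on per-pair counts of hold + lunge, bouts assigned to intervals by onset
with half-open boundaries.

## The synthetic session generator

No raw event logs were deposited for this study, so the package ships a
generator whose defaults encode the study conditions, making every pipeline
stage testable end to end. Each subject runs a semi-Markov process: states
come from an embedded zero-diagonal transition matrix, dwell times from
log-normal distributions (positive skew, matching the separation of bout
durations from transition structure; mean 18–30 s for background states,
under a second for brief events). Three couplings connect the two subjects:

* **High-intensity initiations** arrive as a Poisson stream per individual
  (0.6 h⁻¹ at day 1 rising to 5.5 h⁻¹ at day 6; 3.7 h⁻¹ at day 3, the value
  implied by the published day-3 row totals over 22 individual-hours), 70%
  lunge-led and 30% hold-led. Initiations are realized only when the
  initiator (and for holds, both animals) is in a background state.
* **Hold mirrors immobilized**: every hold bout forces an equal-length
  immobilized bout in the opponent — the two behaviors have identical
  frequency by construction, as in the scored data.
* **Approach responses**: an approach elicits avoid or retreat in a
  background-state opponent with small probabilities (0.06/0.04 at day 3).
  Most approaches elicit no visible response, consistent with the published
  day-1 session narrative.

Mean hold duration rises 2.0 → 8.2 s across ages; background time shares
follow the published ontogeny (walking and standing fall, grooming and
upside-down rise; the four states stay at or above 96% of session time at
every age). Retreats split evenly between pair members because the two
subjects run symmetric processes — no dominance is built in — and
initiation rates are time-homogeneous, so encounters are stationary (no
escalation). Single-male configurations drop all interactive behaviors plus
bobbing and jump, and stilt peaks at day 3, as seen in isolated controls.

Because couplings interrupt bouts, the observed sequences are the embedded
chain *thinned* by the interruption rate plus the insertion transitions the
couplings create. `implied_transition_probs()` computes this implied
row-normalized matrix analytically from a configuration: for background
state $x$ with survival $s_x = E[e^{-\rho D_x}]$ (interruption rate $\rho$,
log-normal dwell $D_x$), row $x$ becomes $s_x P_{x\cdot} + (1-s_x) w$ with
$w$ the insertion-type distribution; entry rates and time shares are solved
jointly by fixed-point iteration. Parameter-recovery tests compare cohort
matrices against this implied matrix — the deterministic image of the
configuration — rather than the raw embedded rows. Rarely entered states
(immobilized, jump, bobbing, stilt, lunge, hold, wrestle, low-intensity
aggression, turn toward) are given deterministic exit rows in the defaults:
their conditional distributions could not be estimated from cohort-sized
samples anyway, and low-entropy exits keep the configuration identifiable
at the study scale.

What the generator does *not* emulate: true inter-fly response latencies and
dwell-time shapes (unknowable without the raw data), lunge→hold compound
attacks, and any fight-outcome feedback. Passing tests therefore demonstrate
that the pipeline's statistics are correct and calibrated on data with the
study's structure — not that the generator is a behavioral model of the
animal.

## Problem sizes, tie-breaks and degenerate inputs

The test suite exercises the pipeline at the study's own scale (11 pairs
per cohort, 10 on day 4, 60-minute sessions) and uses 200-pair cohorts for
parameter recovery, 100 cohorts for enrichment detection, and 200
replicates for null-calibration checks; Monte-Carlo size checks of the
G tests use $k = 6$ chains with 500 replicates. Ties in rank tests use the
standard mid-rank correction. Bouts with zero duration (point events) are
legal; adjacent same-behavior records merge only when contiguous, while a
coded gap leaves two bouts but no self-transition (sequences collapse runs
at extraction). All-zero rows or columns make the corresponding
quasi-independence margins fit trivially to zero, with a warning rather
than an error, since small cohorts legitimately lack rare behaviors.
Half-open binning rules (node frequency classes, deviate arrow bands,
interval assignment, dominance histogram) each fix one boundary convention
and are asserted in the tests. Kinematic node sizes use first-member (row)
marginal frequencies; row and column margins are nearly identical for these
matrices and the original figures do not state which was used.
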