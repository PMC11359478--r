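---
title: "Weighting criteria and ranking climate-sensitive zoonoses with fuzzy AHP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting criteria and ranking climate-sensitive zoonoses with fuzzy AHP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoonoprior)
```

## The problem

Health agencies that want to prepare for climate change need to know which
zoonotic diseases in their jurisdiction are most sensitive to it. Because
direct evidence linking climate hazards to disease burden is sparse, the
standard instrument is a structured expert-elicitation workshop: a One
Health panel (typically 6–15 experts) agrees on prioritization criteria,
weighs them, answers scoring questions for each candidate disease, and the
answers are aggregated into a ranked priority list. `zoonoprior`
implements the quantitative machinery of such a workshop — everything
between the raw expert judgments and the ranked list — together with a
seeded simulator so the whole pipeline can be exercised and tested without
running a workshop.

Criteria come in three sets reflecting the causal chain from climate to
health: climate **hazards** (warming, floods, droughts, ...), biological
**transmission** processes they act on (geographic exposure, host/vector
demographics, pathogen evolution, host susceptibility), and health
**outcomes** (severity, controllability, transmissibility, socio-economic
impact). A packaged default vocabulary is available via
`default_vocabulary()`; real workshops refine it.

## Criterion weighting: crisp AHP

Each expert compares every pair of criteria within a set on a nine-phrase
linguistic scale ("equally important" ... "extremely more important"),
translated to Saaty intensities $\{1/9, 1/7, 1/5, 1/3, 1, 3, 5, 7, 9\}$.
One judgment per unordered pair fills a positive reciprocal matrix $A$
with $a_{ii}=1$ and $a_{ji}=1/a_{ij}$.

Crisp weights use the row geometric mean,
$w_i \propto \big(\prod_j a_{ij}\big)^{1/n}$, normalized to sum 1. The
principal-eigenvector derivation (power iteration) is available as an
option; the two coincide exactly on consistent matrices and agree to
within 0.01 per component on every matrix that passes the consistency
gate in our simulations. The geometric mean is the default because it is
the basis of the fuzzy extension below and reproduces the published
example table.

Judgment coherence is screened with Saaty's consistency ratio. With
$\lambda_{\max}$ estimated as the mean of $(Aw)_i/w_i$,
$CI = (\lambda_{\max}-n)/(n-1)$ and $CR = CI/RI(n)$, where $RI$ is the
expected $CI$ of random matrices (classic table, extended to order 15 and
swappable as data). Matrices with $CR \ge 0.10$ are refused by the
pipeline step `run_weights()` — mirroring elicitation interfaces that
only let a participant save an acceptably consistent matrix — while the
library-level `consistency()` merely flags them, so analysts can inspect
rejected matrices. Orders 1 and 2 are consistent by construction
($CR = 0$).

Group weights aggregate the participants' matrices by the element-wise
geometric mean, the aggregation that preserves reciprocity, and re-derive
weights from the group matrix.

## Fuzzy weights

Expert judgments are imprecise; carrying that imprecision into the
weights is the point of the fuzzy extension. Each crisp intensity is
widened into a triangular fuzzy number (TFN) $(l, m, u)$ one scale step
either side of the mode: $1 \to (1,1,1)$ (equal importance has no
spread), $x \to (x-1, x, x+1)$ for integer $x$ with saturation at the
scale ends ($9 \to (8,9,9)$), and reciprocals map to fuzzy reciprocals
$(1/u, 1/m, 1/l)$. This ±1 spread is the package default and is validated
end to end against the published example table; the scale is an argument
(`scale =`) wherever fuzzification happens, and the degenerate embedding
$x \to (x,x,x)$ collapses the whole fuzzy pipeline back to the crisp
geometric-mean weights, which the tests check as a closed-form limit.
The TFN for intensity 9 saturates at the upper scale end rather than
extending to 10; it is the one scale point the packaged example never
exercises, so saturation was chosen for symmetry with the lower end.

Fuzzy weights follow Buckley's geometric-mean construction: componentwise
row fuzzy geometric means $\tilde r_i$, then
$\tilde w_i = \big(l_{r_i}/\sum_j u_{r_j},\; m_{r_i}/\sum_j m_{r_j},\;
u_{r_i}/\sum_j l_{r_j}\big)$, the extremal quotient that brackets the
crisp weight. Two invariants follow and are tested: the modes equal the
crisp geometric-mean weights exactly, and $l_i \le m_i \le u_i$ with
modes summing to 1.

Defuzzification is by centroid, $(l+m+u)/3$; centroids do not sum to 1,
so a final normalization divides by their total. Reports show both
columns at full precision plus 2-decimal display columns rounded half
away from zero.

For group fuzzy weights the participants' matrices are fuzzified first
and then aggregated componentwise by geometric means, mirroring the crisp
group path. The ordering matters for a practical reason: crisp group
entries are geometric means and generally lie off the Saaty scale, so
they could not be fuzzified afterwards. Defuzzified group weights are
normalized after aggregation.

## Scoring diseases

Questions combine one criterion from each set ("Does *warming* impact
the *evolution of pathogens* and lead to an increase in *mortality*?")
and carry ordered multinomial answer options with consecutive integer
values starting at 0 (the "no change" anchor) — so an answer $V_{q,d}$
out of a maximum $M_q$ contributes the fraction $V/M$ of the question's
weight. The question weight $w_q$ is the arithmetic mean of its three
normalized defuzzified criterion weights.

For participant $p$, disease $d$ and question $q$:

$$Z_{q,d} = w_q \frac{V_{q,d}}{M_q}, \qquad
  Z_{low,q,d} = w_q \frac{V_{q,d} - C_{q,d}}{M_q}, \qquad
  Z_{high,q,d} = w_q \frac{V_{q,d} + C_{q,d}}{M_q},$$

where $C_{q,d}$ is the integer half-width attached to the expert's
confidence label. The default mapping is high → 0, medium → 1, low → 2:
only the medium value is anchored by the published worked example, so the
outer two are a package decision — the smallest monotone integer widths
around it — and the mapping is configurable per workshop. $V - C$ and
$V + C$ are clamped into $[0, M_q]$ before scaling, so bounds stay in
$[0, w_q]$; the worked example (w = 0.37, V = 2, C = 1, M = 3, giving
0.25 and the range 0.12–0.37) never triggers the clamp, so clamping
changes nothing where the formulas are exercised in print while
preventing out-of-range scores elsewhere.

Disease totals sum over participants and questions,
$Z_d = \sum_p \sum_q Z_{q,d,p}$, likewise for the bounds. Normalized
scores divide by $P \cdot \sum_q w_q$ — the total attained when every
participant gives the maximum answer everywhere — so the normalized
initial score has ceiling exactly 1 (attained iff all answers are
maximal) and floor 0. This constant reconciles the two ways aggregate
scores are usually presented: as sums and as per-participant means with
maximum 1. Ranking is by normalized initial score descending, ties
broken by the lower bound descending and then disease id, making the
ranking a deterministic function of the score set.

Missing (participant, disease, question) triples are an error by default
— workshops require complete answering — with an explicit
`missing = "zero"` option that imputes answer 0 at low confidence and
reports the imputed rows.

## The synthetic workshop generator

`simulate_workshop()` emulates an elicitation workshop end to end from a
single seed. Its defaults are the documented illustrative scenario: 10
experts, 10 questions, 25 diseases, four criteria per set, four answer
options per question.

* **Judgments.** Each expert's "true" weights are a normalized
  Gamma(2, 1) draw on the simplex (a Dirichlet(2) draw); the consistent
  ratio matrix $w_i/w_j$ is perturbed entrywise by multiplicative
  lognormal noise (default sd 0.15 on the log scale, a moderate
  disagreement level under which roughly the intended share of draws
  passes the gate), snapped to the nearest odd Saaty value *in log
  space* (ratios are multiplicative, so log distance is the right
  metric), mirrored, and redrawn until $CR < 0.10$ (bounded retries with
  a diagnostic error when the budget is exhausted).
* **Answers.** Each disease gets a latent climate-sensitivity score
  $s_d \sim U(0,1)$. An answer is a discretized logistic draw: noise
  (default sd 1.0) is added to $\mathrm{logit}(s_d)$ and the resulting
  proportion is scaled by $M_q$ and rounded. The model is monotone in
  $s_d$ by construction, collapses to $V = \mathrm{round}(s_d M_q)$ at
  zero noise, and no generative model is prescribed by the elicitation
  protocol itself — simplicity and monotonicity were the criteria.
* **Confidence.** Labels are sampled with probabilities 0.3/0.5/0.2 for
  high/medium/low, a panel that is mostly moderately confident.

What the simulator does *not* model: correlated expert opinion, expert
bias structures, question-specific difficulty, or any real epidemiology —
latent sensitivity is a scalar. Passing tests therefore demonstrate that
the pipeline's arithmetic and plumbing are correct and that rankings
recover a monotone latent signal; they say nothing about the validity of
real expert elicitations.

## Numerical choices and degenerate inputs

* Reciprocity is validated at tolerance $10^{-9}$; group aggregation
  re-symmetrizes in log space against floating-point drift.
* Power iteration converges to $10^{-12}$ by default with a capped
  iteration count and diagnostic error.
* Weight vectors must be strictly positive before consistency is
  computed; a 1×1 criterion "set" gets fuzzy weight (1, 1, 1) and weight 1.
* Display rounding is half away from zero at 2 decimals; full precision
  is retained everywhere internally.
* Intermediate even intensities (2, 4, 6, 8) are accepted on input for
  interoperability with generic AHP data, though the linguistic scale
  produces odd values only.

## Problem sizes used in the test suite

Unit and property tests run on workshops of 2–6 participants, 3–10
diseases and 2–6 questions; the rank-recovery check uses the full
default scenario (10 × 10 × 25) plus panels of 2 and 15 experts over
three seeds. These sizes were chosen as the smallest at which every
property (reciprocity, additivity against a brute-force double loop,
monotonicity, normalization ceiling, recovery) is non-trivially
exercised; the whole suite completes in a few seconds.

## Limitations

* No incomplete-matrix imputation and no alternative consistency indices
  (geometric consistency index, Koczkodaj); inconsistent matrices must be
  re-elicited.
* No fuzzy extent analysis (Chang's method) or general fuzzy-set algebra
  beyond positive TFNs; defuzzification is centroid-only.
* No statistical test of rank separation between diseases: overlapping
  confidence ranges are displayed, not tested.
* Group aggregation assumes equally weighted experts.
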