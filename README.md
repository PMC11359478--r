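# zoonoprior

Fuzzy analytic-hierarchy-process (FAHP) weighting and confidence-adjusted
scoring for prioritizing climate-sensitive zoonoses.

## What it is for

Disease-control agencies rank zoonoses by how sensitive their transmission
is to climate change, usually through a structured expert workshop: a One
Health panel weighs prioritization criteria by pairwise comparison,
answers ordinal scoring questions for each candidate disease, and attaches
a confidence level to every answer. `zoonoprior` is the computational
engine for that process, aimed at epidemiologists and One Health analysts
running or studying such elicitations. It covers:

* the nine-phrase linguistic judgment scale and its Saaty intensities;
* pairwise-comparison matrices, geometric-mean and principal-eigenvector
  weights, and Saaty's consistency-ratio gate (CR < 0.10);
* Buckley triangular-fuzzy-number weights, centroid defuzzification and
  normalization, carrying judgment imprecision into the weights;
* group aggregation across experts by element-wise geometric means;
* question weighting (mean of the three constituent criterion weights)
  and confidence-adjusted disease scoring with a normalized ranked output;
* a fully seeded synthetic-workshop generator for testing and simulation
  studies.

## The model in brief

Each expert fills a positive reciprocal matrix $A$ ($a_{ji} = 1/a_{ij}$)
per criterion set. Crisp weights are normalized row geometric means
$w_i \propto (\prod_j a_{ij})^{1/n}$; consistency is screened with
$CR = CI/RI$, $CI = (\lambda_{\max}-n)/(n-1)$. For fuzzy weights each
intensity $x$ becomes the triangular fuzzy number $(x-1, x, x+1)$
(saturating at the scale ends), row fuzzy geometric means $\tilde r_i$
give Buckley weights
$\tilde w_i = (l_{r_i}/\sum u,\ m_{r_i}/\sum m,\ u_{r_i}/\sum l)$,
defuzzified by centroid $(l+m+u)/3$ and normalized.

A question $q$ referencing one hazard, one transmission process and one
outcome gets weight $w_q$ = mean of the three criterion weights. An
answer of value $V \in \{0,\dots,M_q\}$ at confidence half-width $C$
scores

$$Z = w_q V / M_q, \quad Z_{low} = w_q (V-C)/M_q, \quad
Z_{high} = w_q (V+C)/M_q$$

(clamped to $[0, M_q]$), summed over participants and questions per
disease and normalized by $P \sum_q w_q$ so the best attainable score
is 1.

## Worked example

Weighting four climate hazards from one expert's six pairwise judgments:

```r
library(zoonoprior)
m <- example_hazard_matrix()   # packaged 4x4 example judgment set
weight_report(m)
#> Criterion weights for set 'hazard' (crisp method: gm)
#>       criterion weight fuzzy_l fuzzy_m fuzzy_u defuzzified normalized_defuzzified
#>         warming 0.1010  0.0709  0.1010  0.1471      0.1064                 0.1030
#>        flooding 0.6502  0.4912  0.6502  0.8571      0.6662                 0.6451
#>         drought 0.1904  0.1281  0.1904  0.2738      0.1974                 0.1912
#>  sea_level_rise 0.0583  0.0422  0.0583  0.0875      0.0627                 0.0607
#> Consistency: lambda_max = 4.2278, CI = 0.0759, RI = 0.90, CR = 0.0844 (acceptable, CR < 0.10)
```

Flooding dominates (weight 0.65) and its fuzzy triple (0.49, 0.65, 0.86)
shows how much imprecision the ±1 judgment spread induces; the matrix
passes the CR < 0.10 gate, so this expert's judgments are coherent enough
to use.

Scoring one answer — question weight 0.37, answer 2 of a maximum 3,
medium confidence (C = 1):

```r
question_score(0.37, 2, 3)      # 0.2467
score_bounds(0.37, 2, 1, 3)     # 0.1233 0.3700
```

i.e. an initial score of 0.25 ranging from 0.12 to 0.37 at 2 decimals.

A full synthetic workshop, end to end:

```r
ws <- simulate_workshop(workshop_sim_config(seed = 1))  # 10 experts, 10 questions, 25 diseases
w  <- run_weights(ws$judgments, ws$config)              # gate + group FAHP weights
r  <- run_rank(ws$responses, w, ws$config)              # scores, bounds, ranking
r$ranked
#> Priority list: 25 diseases, 10 participants, 10 questions
#>  rank    disease score   low  high
#>     1 disease_17 0.994 0.701 0.997
#>     2 disease_05 0.968 0.677 0.990
#>     3 disease_06 0.946 0.649 0.981
#>  ...
```

`score` is the normalized initial estimate (maximum 1); `low`/`high` are
the aggregated confidence bounds. `plot_priority(r$ranked)` draws the
dot-and-range chart.

Batch use from a shell goes through the thin CLI wrapper
(`inst/cli/zoonoprior.R`) with subcommands `validate`, `weights`,
`score`, `rank` and `simulate`; every run writes a `run_manifest.json`
recording inputs, digests, seed and options.

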