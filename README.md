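# comorbnet

Pattern analysis of multimorbidity — the co-existence of two or more
chronic conditions — in survey cohorts. `comorbnet` is aimed at
epidemiologists working with subject-by-condition tables (one row per
participant with a sex stratum, a survey weight and K binary condition
indicators) who want to move beyond per-condition prevalence to the
*structure* of disease co-occurrence: which pairs and triads of
conditions occur together more often than chance, and how the resulting
comorbidity network organises into disease communities.

## The statistic at the core

Association rules A ⇒ B over condition pairs are scored by support
P(A,B), confidence P(B|A) and lift

    Lift(A ⇒ B) = P(A,B) / (P(A) P(B)),

the observed/expected ratio, equal to 1 under independence. Because the
attainable range of the lift depends on the margins (the joint is
confined to the Fréchet interval, and an observed rule has support at
least 1/n), a fixed lift threshold is biased toward rare conditions. The
**standardised lift** removes the bias by rescaling onto [0, 1]:

    StdLift(A ⇒ B) = (Lift − λ) / (υ − λ)

    λ = max{ P(A)+P(B)−1, 1/n, s, c·P(A) } / (P(A) P(B))
    υ = 1 / max{ P(A), P(B) }          ("corrected", the default)

with support/confidence floors s = c = 0 by default. Rules with
standardised lift above 0.2 are retained, mined per sex stratum, and
assembled into an undirected comorbidity network (nodes: conditions,
sized by weighted prevalence; edges: weighted by co-occurrence counts)
that is partitioned by fast-greedy modularity maximisation. A
latent-Gaussian (Gaussian copula) simulator generates cohorts with known
margins, calibrated planted dependence and survey weights, so the whole
pipeline is testable against ground truth.

## Worked example

Score the canonical female hypertension / high-cholesterol pair from its
published inputs — margins 42.61% and 52.31%, joint prevalence 26.2%,
stratum size 3,347:

```r
library(comorbnet)
rule_metrics(0.4261, 0.5231, 0.262, 3347)[, c("lift", "std_lift")]
#>      lift  std_lift
#> 1 1.17549 0.6146089
```

The pair co-occurs ~18% more often than expected under independence
(lift 1.18), and relative to what its margins allow, the association
sits at 0.61 on the [0, 1] standardised scale — above the 0.2 retention
threshold.

The numbered drivers under `analysis/` run the study-scale workflow on a
simulated cohort of 6,101 subjects (2,754 male / 3,347 female, 31
conditions with realistic margins and block-structured dependence):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_prevalence.R
Rscript analysis/03_mine_rules.R
Rscript analysis/04_network_communities.R
Rscript analysis/05_threshold_sensitivity.R
```

which prints, among other things:

```
weighted multimorbidity prevalence (>= 2 conditions): 76.63%
condition-free: 7.52%; median count: 3; max count: 14
male: 296 rules retained at std lift > 0.2; most prevalent retained
  pair: high_cholesterol & hypertension (support 29.0%, std lift 0.63)
female: network of 31 conditions / 187 edges; 4 communities,
  modularity Q = 0.056
```

— over three quarters of simulated older adults are multimorbid, the
median subject carries 3 of the 31 conditions, hypertension and high
cholesterol form the most prevalent retained comorbidity in both sexes,
and the detected communities recover the cardiometabolic,
musculoskeletal/frailty and sensory blocks planted by the simulator.
Tables land in `results/analysis/`. The same stages are available
programmatically via `run_pipeline()`, which also writes a manifest
making every output reproducible byte-for-byte.

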