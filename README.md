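# limbicnet

Where in the limbic system does a systemically administered anxiolytic act?
`limbicnet` answers a computational version of that question for
immediate-early-gene (c-Fos) mapping experiments: it ranks brain regions by
how strongly a drug *decouples* their activity from the rest of the network,
by fusing region-wise activation profiles with a directed, weighted
anatomical connectome. A second pipeline scores deep-brain calcium imaging
recordings from paired saline/drug sessions at single-unit resolution.
Synthetic generators with planted ground truth make both pipelines testable
end to end, without access to any animal data.

The package is aimed at systems-neuroscience labs running drug ×
behavioral-state c-Fos screens (or re-analyzing published ones) and at
anyone who wants a self-contained, validated reference implementation of
connectome-weighted node scores.

## The network scores

For a screen with two drug states (saline, drug) crossed with four anxiety
conditions (none, EPM, shock, shock & EPM):

1. c-Fos expression is averaged within each treatment group, and per-region
   *z*-scores are computed over the treatment groups (population SD). A
   home-cage group, if present, participates only in hierarchical
   clustering of the groups, never in the scores.
2. Per drug state, each region gets a 4-vector of *z*-scores over the
   anxiety conditions, and all pairwise Pearson correlations ρ between
   region vectors are collected into a per-state correlation matrix.
3. The per-region correlation sum **φ = Σρ** (self-correlation excluded)
   measures how strongly a region co-varies with the whole network;
   **Δφ = φ_drug − φ_saline** is the drug effect on that coupling.
4. The connectome is normalized to each region's outgoing edges
   (**Σζ_out = 1**) and the correlations are weighted by connection
   strength: **φ_con = Σρζ**, restricted to first-order anatomical
   neighbors, with an Output variant (over outgoing edges) and an Input
   variant (over incoming edges). **Δφ_con = φ_con(drug) − φ_con(saline)**
   ranks regions by drug-induced (de)coupling from their anatomical
   neighborhood.

## The calcium event pipeline

Per unit and session: ΔF/F₀ normalization (F₀ = 10th percentile),
zero-phase 2 Hz low-pass filtering, event detection at a threshold of
6 robust noise SDs with a decay-time gate τ > 0.5 s, the session **event
score** (cumulative amplitude of detected events), and classification of
each unit as increasing / decreasing / unaffected by the sign of the
drug-minus-saline score difference. A Pearson χ² test associates response
class with cell type.

## Worked example

```r
library(limbicnet)

# a screen with a fully decoupled planted region (CEA) and a toy connectome
sim  <- simulate_cfos(cfos_sim_config(decoupling = 1, drug_effect = -30, seed = 42))
conn <- simulate_connectome(limbic_regions(), density = 0.5, seed = 42)
fit  <- cfos_network_scores(sim$expression, conn)
fit
#> c-Fos network analysis: 15 regions, 9 groups
#> top region by |delta phi_con (output)|: CEA

head(fit$scores[order(fit$scores$rank_delta_phicon_out),
                c("region", "delta_phi", "delta_phicon_out", "delta_phicon_in")], 5)
#>  region delta_phi delta_phicon_out delta_phicon_in
#>     CEA   -15.789           -1.079          -1.505
#>    ACAd    -1.124           -0.240           0.022
#>      LA    -1.156           -0.226          -0.240
#>     LSv    -1.105           -0.185           0.009
#>     LSc    -1.020           -0.164          -0.144
```

The planted region (CEA) loses essentially all of its correlation with its
anatomical neighbors under drug — its Δφ_con ≈ −1 is the normalization
bound — while every other region moves only by noise. The same analysis on
real data takes an expression table (`read_expression()`) and a connectome
edge list (`read_connectome()`) in plain tab-delimited text.

```r
cal <- simulate_calcium(calcium_sim_config(n_units = 4,
                                           event_rate = c(saline = 3, drug = 1),
                                           seed = 42))
res <- calcium_event_analysis(cal$traces$saline, cal$traces$drug, fps = cal$fps)
res$summary[, c("unit", "score_saline", "score_drug", "class")]
#>   unit score_saline score_drug      class
#>  unit1        1.091      0.255 decreasing
#>  unit2        0.879      0.000 decreasing
#>  unit3        1.413      0.000 decreasing
#>  unit4        0.000      0.381 increasing
```

With the drug lowering the planted event rate from 3 to 1 per session, most
units classify as decreasing.

A command-line entry point wrapping these functions ships at
`inst/cli/limbicnet` (subcommands `simulate`, `analyze`, `calcium`,
`recover`).

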