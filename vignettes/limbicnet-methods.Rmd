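---
title: "Methods: connectome-weighted decoupling scores and calcium event detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-weighted decoupling scores and calcium event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbicnet)
```

# The scientific problem

A systemic anxiolytic reaches every brain region at once, so a raw
activation map (which regions go up or down) cannot localize its site of
action. The approach implemented here asks a sharper question: under drug,
which region stops *co-varying* with the rest of the network the way its
anatomy says it should? A region can keep an unremarkable mean activity
while its coupling to its anatomical neighbors collapses — and that
decoupling is the candidate drug target signature.

`limbicnet` implements two pipelines around this idea: the c-Fos network
analysis that produces the per-region decoupling scores, and the deep-brain
calcium event pipeline that quantifies single-unit activity changes in
paired saline/drug sessions.

# The network model

The experimental design is a crossing of two drug states
(`saline`, `DZP`) with four anxiety conditions (`none`, `EPM`, `shock`,
`shock_EPM`), plus an optional home-cage group. Given per-animal expression
values, the analysis proceeds in four steps.

**Step 1 — group means and z-scores.** Expression is averaged within each
(region, group) cell, then each region row is standardized over the
treatment groups: `z = (m − mean) / sd`, with the *population* SD (divide
by N). The population form is deliberate: the eight group means are the
complete set being standardized, not a sample from a larger population; a
`sd_type = "sample"` switch exists for comparison. The standardization
scope is the eight crossed groups by default (`zscore_scope = "crossed"`);
a home-cage group is projected with the same per-region center and scale
so that one standardized profile can feed both clustering and correlation.
The scope can be widened to all nine groups (`"all"`) — the choice shifts
every z-score of a region by a common affine map and therefore leaves all
between-region Pearson correlations, hence all φ scores, unchanged; it
matters only for the dendrogram's distances.

**Step 2 — per-state correlation matrices.** For each drug state, every
region is reduced to its 4-vector of z-scores over the anxiety conditions,
and all pairwise Pearson correlations between region vectors are computed.
With only four support points a sample correlation is a coarse quantity —
under independence it is uniformly distributed on [−1, 1] — which is why
the drug-vs-saline *difference* of aggregate scores, not any single ρ,
carries the inference. A region whose 4-vector is constant has no defined
correlation; those entries are set to 0, flagged, and warned about rather
than propagating NaN, so a degenerate region contributes neutrally.

**Step 3 — φ and Δφ.** φ(i) = Σ_{j≠i} ρ(i, j). Self-correlation is
excluded: ρ(i, i) = 1 would add the same constant to every region and
cancel in Δφ anyway, and excluding it gives the clean bound |φ| ≤ R − 1.
Δφ = φ_drug − φ_saline.

**Step 4 — φ_con and Δφ_con.** The directed connectome is normalized to
each source's outgoing edges (Σζ_out = 1), then
φ_con(i) = Σ_j ρ(i, j)·ζ over region i's first-order neighbors: outgoing
edges for the Output variant, incoming edges for the Input variant. The
Input variant reuses the out-normalized weights ζ(j→i) without
re-normalizing over incoming edges — the normalization happens once, on
the out-edges, and the Input sum is then a projection-strength-weighted
sum of what a region *receives*; a re-normalized variant would change only
the per-region scale, not the ranking logic, and is not implemented as a
default to keep the two variants on one common weight scale. Missing edges
contribute 0 (no imputation). After out-normalization |φ_con Output| ≤ 1;
the Input sum is bounded by the total incoming normalized weight.

Regions are ranked by absolute score by default (a strong *de*coupling is
as informative as a strong coupling); signed ranking is available. Ties
break lexicographically so ranks are deterministic.

**Clustering.** The group dendrogram uses average linkage on Euclidean
distances between the groups' region-wise z-vectors. Linkage and metric
are configurable and no claim is attached to the tree's fine topology; the
dendrogram is a descriptive display, and the home-cage group participates
here only.

# The synthetic c-Fos generator

No raw data accompany the analysis, so the generator is the package's
test bed and defines its study conditions. Latent group means follow a
single-factor additive model

```
mean(region, state, condition) = baseline + drug_effect·[state = drug]
                               + loading(region) · level(condition)
```

with baseline 100 expression units, drug_effect −30 (the drug lowers
expression; the magnitude is a package choice), anxiety levels
(0, 0.5, 1, 1.5) for (none, EPM, shock, shock & EPM) forming a monotone
anxiety-load gradient, and positive per-region loadings spaced over
30–60. One shared anxiety factor with positive loadings means every
region's latent 4-vector is a scaled copy of the level pattern, so all
latent between-region correlations are +1 — a deliberately clean backdrop
against which a planted decoupling is unambiguous. Animal-level values add
iid Gaussian noise (SD 10) and truncate at zero; n = 4 animals per group.

The planted effect blends the *target* region's drug-state latent means
with an independent random profile of matching location and spread, in
proportion to `decoupling` ∈ [0, 1]. Only the drug state is touched —
the saline structure stays intact, which is exactly what the Δ scores
contrast. Because the profile is genuinely independent (not orthogonalized
against the anxiety pattern), a fully decoupled target can still correlate
with its neighbors by chance in a minority of seeds; the recovery
experiment below quantifies this.

What the generator does *not* emulate: counting noise from
immunohistochemistry (values are Gaussian, not count-distributed),
between-animal correlation structure, regional covariance beyond the one
shared factor, and any true anatomical connectome (the toy connectome is
an Erdős–Rényi digraph with uniform weights). Passing tests therefore
demonstrate correctness of the *computation* and recoverability of a
planted effect under clean conditions — not that the scores are robust to
every pathology of real histology data.

# The recovery experiment

`run_recovery()` repeats generate → analyze over consecutive seeds and
reports the fraction of runs in which the target ranks first. Under the
acceptance conditions (decoupling 1, drug_effect −1, noise SD 10 = 10% of
baseline, density-0.5 connectome, 15 regions, 50 seeds) the target ranks
first by |Δφ_con Output| in ≈96% of seeds; with decoupling 0 the rank-1
fraction sits at the chance level 1/15 over 100 seeds. All child seeds
derive from the root seed by increment, so reports are reproducible.

# The calcium pipeline

**ΔF/F₀.** F₀ is the session's 10th-percentile fluorescence — robust to
sparse positive transients; the percentile is configurable. For Gaussian
baseline noise this estimator sits a known ≈1.28 noise-SDs below the true
baseline; downstream amplitudes are measured relative to the trace median,
and at the default noise level (2% of baseline) the residual scale bias is
≈2.6%, well inside the pipeline's validated 10% score accuracy.

**Filtering.** Zero-phase 4th-order Butterworth low-pass at 2 Hz
(`filtfilt`, so the effective response is |H|²). Zero-phase matters: a
causal filter would delay peaks and bias decay-time estimates. The
implementation pads the trace by odd reflection (10·fps/cutoff samples)
before filtering, which absorbs the filter's startup transient; without
padding, edge artifacts of several percent leak into the first seconds of
the trace. DC gain is exactly 1.

**Detection.** Noise SD is estimated as MAD × 1.4826 of the filtered
trace (robust, so events do not inflate their own threshold; plain SD is
available). Candidate events are excursions above
`median + 6·SD`, with two structural corrections, both standard in
transient detection:

* *Hysteresis*: an excursion extends until the trace falls below a lower
  release threshold (2 SD). Without it, the decaying tail of a genuine
  event re-crosses the 6 SD line on noise and produces duplicate
  detections (observed as a ~7% false-positive rate on synthetic traces).
* *Prominence splitting*: one excursion can hold several transients riding
  on each other's tails; it is split wherever two local maxima are
  separated by a dip at least 6 SD below the smaller peak. Without it,
  ~5% of planted transients merge and are undercounted.

Per event, amplitude is the maximum of the *unfiltered* ΔF/F₀ trace in the
event's segment (the 2 Hz filter attenuates a τ = 1 s transient peak by
≈10%, so reading amplitude off the filtered trace would bias every score);
the decay time τ is measured on the filtered trace as time from peak to
1/e of peak height, which is empirically exact for τ = 1 s at 20 samples/s.
Events with τ ≤ 0.5 s are discarded — the gate that separates calcium
transients from fast artifacts. Both thresholds, the filter cutoff, and
the gate are parameters with the defaults above.

**Scores and classification.** The event score is the session's summed
event amplitudes; units classify by the exact sign of the drug-minus-saline
difference (increasing / decreasing / unaffected). Exact-zero comparison is
kept as the default because a unit with no detected events in either
session — common in sparse recordings — is genuinely "unaffected"; an
optional tolerance band exists for real-valued near-ties. The cell-type ×
class association uses Pearson's χ² without continuity correction,
dropping classes that are empty across all cell types (df shrinks
accordingly).

**Synthetic traces.** Transients have instantaneous rise and exponential
decay (τ = 1 s), Poisson counts (2 per 60 s session), amplitudes Gaussian
around 0.2 ΔF/F₀ (CV 0.1, truncated), noise SD 0.02 ΔF/F₀ — a 10:1
amplitude-to-noise ratio typical of curated GCaMP6 miniscope units — on a
baseline of 100 fluorescence units at 20 samples/s. Onsets snap to the
sample grid and are drawn in [0, duration − 3τ] so every planted transient
completes within its session (a boundary-truncated transient has no
well-defined measurable decay). Under these conditions the detector
achieves precision 1.00 and recall ≈0.97 over 20 seeds (residual misses
are transient pairs closer than the splitting resolution), and summed
event scores land within ≈7% of the planted amplitude sums.

# Numerical and interface choices

* All generators are pure functions of their configuration including the
  seed; the caller's RNG state is restored afterwards.
* Problem sizes in the validation suite — 100 random 15-region instances
  for oracle and bound checks, 50/100 seeds for recovery, 20 seeds × 10
  units for detection — were chosen to keep the full suite under a minute
  on one core while leaving the stochastic checks statistically
  comfortable margins.
* File formats are single-dialect tab-delimited UTF-8 with `.` decimals;
  readers validate headers, types, signs, duplicates and self-edges and
  report the offending line. The 15 default region labels are fixture
  defaults only — every function accepts arbitrary label sets.
* Dendrograms serialize to Newick (via `ape`), merge tables are returned
  alongside for programmatic checks.

# Known limitations

* With four anxiety conditions, individual correlations are extremely
  coarse; the scores are only meaningful as aggregates and the package
  deliberately attaches no significance test to Δφ_con (none is defined
  for this design).
* The Input variant's weight convention (reuse of out-normalized weights)
  is one of two defensible readings; both variants share it here so Output
  and Input are comparable on one scale.
* The event detector assumes isolated-to-moderately-overlapping
  transients; heavily bursting units (inter-event intervals well below τ)
  will undercount, and no spike inference / deconvolution is attempted.
* The synthetic connectome and expression models are intentionally
  minimal; they validate the machinery, not the biology.
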