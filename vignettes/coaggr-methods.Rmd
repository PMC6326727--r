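---
title: "Methods: quantifying combinatorial adhesion with coaggr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying combinatorial adhesion with coaggr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaggr)
```

This vignette documents the models and procedures behind `coaggr`, the
choices made where the underlying assays leave details open, and what the
package's synthetic-data tests do and do not establish about real data.

## The CoAggregation Index

Two differentially labelled cell populations that are mixed and rotated
overnight form aggregates whose colour arrangement reports adhesive
compatibility: incompatible populations segregate into separate
single-colour aggregates, partially compatible ones form aggregates with a
shared internal boundary ("interface"), and compatible ones intermix.

`compute_coag()` quantifies this on a two-channel image. The image is tiled
into non-overlapping squares from the top-left origin; squares extending
past the right/bottom edge are discarded so every analyzed square has
identical area (a partial square would otherwise contribute a noisier
occupancy estimate). A square is *occupied* in a channel when at least 2%
of its pixels exceed that channel's threshold; the default threshold is
Otsu's method per channel, overridable with a fixed cutoff. Squares
occupied in neither channel are "black" and removed; the CoAg index is the
fraction of the remaining squares occupied in both channels. An image with
no occupied squares raises an explicit error rather than returning 0/0.

Parameter choices, all configurable via `grid_spec()`:

* **Square side, default 1.25 × cell diameter.** The tile should be
  "slightly larger than one cell" so that a square can only contain two
  colours when two differently coloured cells genuinely abut; 25% margin
  accommodates off-centre cells without making two-cell squares common.
* **Occupancy fraction 2%.** A single bright stray pixel (bleed-through,
  hot pixel) should not mark a 625-pixel square as occupied; 2% of a
  default square is ~13 pixels, about 4% of one cell's area.
* **"More than one colour" = occupied in both channels** — with two
  channels there is no other reading.
* **Behaviour bands**: CoAg < 0.1 segregation, 0.1–0.2 interface, > 0.2
  intermix. The outer bands are open ("below 0.1", "above 0.2"), so the
  interface band is closed on both ends; `classify_behavior(0.1)` and
  `(0.2)` both return `"interface"`.

The index is invariant to swapping the channels and, when the image
dimensions are multiples of the square side, to rotating both channels
together; both invariances are enforced in the test suite, and the grid
implementation is checked square-for-square against a brute-force pixel
enumeration on random images.

Whether occupancy should be measured on raw or background-subtracted
intensities is not standardized for this assay; `coaggr` measures raw
intensities and leaves background handling to the thresholds.

## Aggregate sizes, speed series, and replicate summaries

`measure_aggregates()` thresholds one channel, labels connected components
with 8-connectivity (the convention of common particle-analysis tools;
implemented over an `igraph` pixel-adjacency graph because the available
image libraries label 4-connected components), and removes components
smaller than `min_cells` (default 3) times the single-cell pixel area —
dividing cells and single bystanders otherwise dominate the size
distribution. The boundary is inclusive: an aggregate of exactly three
cells is kept, since only aggregates *smaller* than three cells are
removed. Retained and discarded areas always sum to the full foreground
area, and raising the cutoff can only reduce the retained count; both are
tested as properties.

`speed_series()` summarizes mean aggregate size per rotation speed
(canonically 15/120/160/200/220 RPM; other labels are retained with a
warning). `summarize_replicates()` implements the two-stage average used
throughout: images within a replicate are averaged first, then the
condition mean and SEM are computed over replicate means, so the
independent electroporation — not the image — is the unit of error. With a
single replicate the mean is reported and the SEM flagged undefined rather
than silently zero. Whether images or replicates should be weighted when
averaging is genuinely open for this assay; the two-stage choice weights
replicates equally regardless of how many images each contributed.

## The constrained gamma–normal mixture caller

Targeted single-cell count panels (e.g. nCounter codesets) include
negative-control genes assumed unexpressed in the profiled cell type. On
the analysis scale `x = log2(count + 1)`:

1. **Null model.** The pooled control values across all cells are fit with
   a gamma distribution Gamma(k, θ) by maximum likelihood
   (`fit_null_from_controls()`). Counts of zero are treated as
   *left-censored* at log2(1.5) — any latent value below that rounds to
   zero — rather than replaced by a small constant: a point mass at an
   epsilon floor empirically drags the MLE toward shape < 1 with a
   spuriously heavy tail, which then corrupts every downstream call. The
   censored likelihood is handled by `fitdistrplus::fitdistcens()` with a
   moment-matched start.
2. **Per-cell EM.** Each cell's values are fit with
   π·Gamma(k, θ) + (1 − π)·Normal(μ_c, σ_c²), the gamma frozen at the
   pooled null — the "constraint" that shares information across cells and
   prevents ill-conditioned per-cell fits. The free parameters are the
   null weight π and the expressed component's μ_c, σ_c.
3. **Calls.** A gene is expressed in a cell iff the posterior probability
   of the expressed component is ≥ 0.5 (boundary inclusive).

Numerical choices in the EM (`fit_cell_mixture()`):

* The M-step updates π, then μ_c (projected onto μ_c ≥ kθ + 0.5 to prevent
  label switching), then σ_c about the projected μ_c; this sequential
  scheme keeps the log-likelihood non-decreasing, which the tests assert
  on every fitted cell to −1e−8.
* σ_c is projected into [0.25, 2] log2 units. The lower floor prevents
  collapse onto a single value; the cap prevents the complementary failure
  mode in which the "expressed" normal widens until it blankets the null
  and every gene drifts toward posterior ~0.5. Both failure modes occur in
  practice on cells with little or no expressed signal.
* Initialization is deterministic: π = 0.7, and μ_c, σ_c from the values
  above the null 95th percentile — the genes that are already implausible
  under the null. Initializing from the data's top quartile instead (a
  natural first choice) proved unreliable: in mostly-null cells the top
  quartile is null, and EM converges to the blanket-normal optimum.
* Convergence: log-likelihood change < 1e−6, at most 500 iterations.
* Zeros are floored at ε = 0.01 *only* for gamma density evaluation
  (the gamma support is strictly positive); the null fit itself uses the
  censored likelihood above.
* Posteriors are monotonized in x (sorted cummax): a larger value never
  receives a lower expressed-posterior. The raw gamma/normal likelihood
  ratio can invert in the far right tail when σ_c is small; the
  monotonized posterior encodes that a higher count is never weaker
  evidence of expression.
* **Fallback.** Cells with fewer than two values above the null 95th
  percentile, cells whose EM does not converge, and cells whose fitted
  μ_c lands below the null 99th percentile (a separation guard: such a
  fit has split the null, not found expression) are called by a simple
  threshold — expressed iff x exceeds the null 99th percentile — and
  flagged `fallback` in the output. Note this rule has a ~1% false-positive
  rate by construction, so an entirely unexpressed panel yields a
  near-zero, not exactly zero, call rate.

`filter_positive_cells()` drops cells in which a marker gene (default
`Notch2`, whose expression indicates a non-neuronal identity in olfactory
preparations) is called expressed; `expressed_count_distribution()`
tabulates per-cell repertoire sizes over a gene panel. Probes with codeset
errors are handled by the `excluded_genes` field of `count_matrix()`, not
hard-coded. `qpcr_call()` implements the orthogonal single-cell qPCR rule:
a gene is on iff Ct ≤ 30, inclusive; missing Ct (no amplification) is off.

Whether the original analysis fit the gamma on raw or log2 counts is not
determinable from the assay description; the log2 choice here matches the
scale on which the data are visualized and the expressed component is
plausibly normal.

## The cell-binding network simulator

The simulator asks whether differential apparent adhesive affinity and
relative expression level suffice to produce the observed mixing
behaviours. Two populations (green and red, 25 cells each by default)
carry integer token pools of hypothetical genes (20 tokens per cell,
split by the expression ratio with a minimum of one token per expressed
gene). Per time step (100 steps; 5 repeats):

1. Bond lifetimes are decremented; expired bonds release their tokens.
2. The cell–bond graph is projected to 2-D with a Fruchterman–Reingold
   layout (`igraph`), refreshed every step so dating probability tracks
   the current network.
3. Cells "speed date": a random matching is drawn with pair weight
   1/(1 + distance), and each matched pair proceeds to a binding attempt
   with probability 0.75 — pairing most but not all cells avoids
   oscillatory network behaviour, and the weight is one concrete choice
   for the stated monotone decrease with layout distance.
4. A proceeding pair binds through one free token drawn from each cell
   with probability proportional to per-gene free-token counts; no free
   token on either side, no bond. Lifetimes: mismatched gene pair 1 step;
   same-gene 3 × (gene affinity / baseline-gene affinity) steps, so the
   baseline gene's homophilic bond lasts 3 steps. Colour never enters the
   dynamics.
5. The instantaneous coaggregation is recorded: for every cell with at
   least one bonded partner, the fraction of its *distinct* partner cells
   of the other colour, averaged over such cells. "Proportion of
   different-colour to same-colour partners" is implemented as the bounded
   fraction different/(different + same), matching the [0, 1] scale of the
   imaging index it mirrors; partner counts are distinct cells, not bonds.

The overall in-silico coaggregation is the mean of the instantaneous
values after a 25% burn-in (the network starts edgeless), averaged over
repeats whose seeds derive deterministically from the master seed. With
two identical populations the expected value is the colour-blind
different-colour fraction 25/49 ≈ 0.510, which the test suite checks
within three Monte Carlo standard deviations.

`sweep_simulation()` scans affinity ratios 1–10 and expression ratios
1:1–20:1 for three preset mismatch scenarios. In the `single_vs_double`
preset the single population carries the *baseline* gene and the
co-expressing population adds the higher-affinity gene; as the affinity
ratio grows, the co-expressing population increasingly self-adheres
through the strong gene and excludes the single population, so the
in-silico coaggregation declines — the trend the sweep test asserts.
Token conservation (bound + free = configured level, per gene) is checked
internally at every step.

The simulator is deliberately not spatial: there is no lattice, no
physics, and no fitting of its parameters to experimental CoAg values, and
like its experimental counterpart it reproduces intermixing regimes more
faithfully than interfacing or segregation.

## Screen analytics

`enumerate_mismatch_pairs()` lists the n(n−1) ordered assays of a mismatch
screen (each assay mixes X-only cells with X+Y co-expressing cells);
`build_coag_matrix()` assembles condition means into the heat-map matrix
with an undefined diagonal (homophilic pairs are redundant).

The **net mismatch score**, score(X) = mean over available partners Y of
M[X,Y] − M[Y,X], summarizes each member's ability to overcome a mismatch
and still coaggregate. The exact aggregation formula behind the original
figure is not recoverable from the assay description; this antisymmetric
row-minus-transposed-column mean is this package's definition, chosen
because it matches the verbal description, sums to zero on complete
matrices, is invariant to adding a constant to all entries, and recovers
planted dominance hierarchies exactly on noise-free synthetic screens.
Gaps are averaged pairwise-complete; ties in the ranking break
alphabetically. Whether the original summary used sums or means, or
normalized by partner count, is unknown — with a complete matrix the mean
and sum rank identically.

`regress_coag_vs_n()` is ordinary least squares of condition-mean CoAg on
the number of co-expressed members, the summary used to show that each
added family member dilutes the focal member's coaggregation.

## The synthetic-data generators

Every generator is a pure function of its scenario, including the seed;
regeneration is bit-identical, and each artifact ships with its ground
truth.

**Images** (`make_aggregate_image()`): cells are filled discs of the
nominal diameter with Gaussian intensity falloff (σ = diameter/4) — the
simplest shape with realistic soft edges for occupancy thresholds — placed
within circular blobs at ~50% packing density, plus additive Gaussian
background noise clipped at zero. Defaults: 1024 × 1024 px fields,
20 px cells, 0.9 μm/px, 50 cells per colour — the scale of a 10×
confocal field, without claiming optical fidelity (no PSF, no 3-D
structure; the assay itself provides no pixel calibration, so these are
explicit choices). Segregated mode places two disjoint blobs ≥ 2 cell
diameters apart; interfaced mode packs the two colours into opposite
halves of one blob; intermixed interleaves them. Across seeds the
measured CoAg ordering segregated < interfaced < intermixed is strict,
with segregated fields in the segregation band and intermixed fields in
the intermixing band. Interfaced fields have a single one-dimensional
contact boundary and land near the segregation/interface border rather
than mid-band — a geometric property of the synthetic blobs, not of the
index. `make_size_fixture()` paints disjoint blobs whose pixel areas are
exact by construction, for particle-size tests.

**Counts** (`make_count_matrix()`): each entry is drawn on the log2 scale
— null entries from Gamma(2, 0.5), expressed entries from Normal(8, 1) —
and back-transformed with round(2^x − 1), clipped at zero. No extra count
jitter is added: the mixture fully specifies the noise, keeping the
generator matched to the caller's model so recovery rates are
interpretable. The default null parameters put the null 99.9th percentile
(counts ~20) below the expressed 0.1th percentile (counts ~30): the
components are well separated in their tails, not merely their means —
with a heavier null tail (e.g. scale 0.8) draws at counts of 50–200 from
"negative" genes are intrinsically ambiguous and even the Bayes-optimal
rule misses the recovery target. The default panel mirrors a targeted
neuronal codeset: 27 genes, of which 8 are the protocadherin-like target
panel, 3 are negative controls (never expressed in truth), and 16 are
fillers; 50 cells whose target-panel repertoire sizes are uniform on 0–7
(mean 3.5). Under these conditions the caller's per-cell repertoire
recovery exceeds 95% exact agreement and controls are called off in
> 98% of entries, pooled over 20 seeds.

**qPCR tables** (`make_qpcr_table()`): "on" entries draw Ct around 24
(truncated below 30), "off" entries are either missing (no amplification,
50%) or above a 33-cycle floor, so the Ct ≤ 30 rule separates them
perfectly by construction.

**Screens** (`make_screen_matrix()`): replicate CoAg values with planted
additive structure base + effect(X) − effect(Y) plus noise, clipped to
[0, 1] with a warning — members with larger effects dominate their
mismatches, so the planted effect ranking is the ground-truth net-mismatch
ranking.

What passing on synthetic data does **not** show: the image generator has
no optics, debris, illumination gradients, or touching-aggregate
ambiguity; the count generator has no probe-specific efficiency,
batch effects, or dropout beyond the mixture itself; the simulator is not
a physical model. Results on real data depend on thresholds and panel
design in ways these fixtures cannot probe.

## Problem sizes

The shipped tests use 1024 × 1024 default images (10 seeds per mixing
mode), 128 × 128 random fields for the 100-seed oracle comparison, 27 × 50
count matrices over 20 seeds, and full 100-step simulations (5 repeats;
the 10-point affinity sweep at 5 repeats is the largest single run). These
sizes give stable statistics for every asserted property while keeping the
whole suite at desk scale.

## Known limitations

* Otsu thresholds assume a bimodal intensity histogram; very sparse or
  saturated fields may need a fixed threshold.
* The caller assumes at least two usable negative-control genes; panels
  without controls cannot be fit.
* The EM's expressed component is a single normal; bimodal expressed
  populations within one cell are not modelled.
* The simulator's dating kernel, token granularity, and layout algorithm
  are stand-ins for unspecified originals; conclusions should rest on
  trends across its parameter grid, not absolute values.
* Statistical testing (paired t-tests, ANOVA) is intentionally out of
  scope; the summaries are exported for standard tools.
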