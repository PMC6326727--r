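# coaggr

Quantitative tools for two-colour cell coaggregation assays and targeted
single-cell expression panels, built for studies of combinatorial adhesion
codes such as the δ-protocadherin (δ-Pcdh) family.

In a coaggregation assay, two differentially labelled (red/green)
non-adherent cell populations are electroporated with adhesion molecules,
mixed, and gently rotated overnight; how thoroughly the colours mix in the
resulting aggregates reports on the adhesive compatibility of the expressed
molecules. This package implements the computational arm of such studies:

* **CoAggregation Index (CoAg).** Each two-channel aggregate image is tiled
  into squares slightly larger than one cell (side = 1.25 cell diameters by
  default). Squares occupied in neither channel ("black") are discarded, and

  CoAg = (# squares occupied in both channels) / (# occupied squares).

  CoAg < 0.1 indicates segregation of the two populations, 0.1–0.2
  interfacing along a shared boundary, and > 0.2 increasing intermixing.
* **Aggregate size measurement.** Threshold, 8-connected component
  labelling, and removal of aggregates smaller than three cells
  (area < 3 × single-cell area), with sizes in pixels, cells, and μm²;
  plus speed-series summaries (mean aggregate size vs rotation RPM) and
  two-stage replicate summarization (images → replicate → condition,
  mean ± SEM over replicates).
* **Constrained gamma–normal mixture expression calling.** For a
  genes × cells count panel with designated negative-control genes, the
  null (not-expressed) distribution is a gamma fitted on pooled
  log2(count+1) control values; each cell is then fit by EM with the
  mixture π·Gamma(k, θ) + (1−π)·Normal(μ_c, σ_c²), the gamma frozen at the
  pooled fit — the constraint that shares information across cells. A gene
  is called expressed in a cell when its posterior probability of the
  expressed component is ≥ 0.5. Includes marker-positive cell filtering
  (e.g. Notch2⁺), per-cell expressed-count distributions, and the
  qPCR rule (on ⇔ Ct ≤ 30).
* **Monte Carlo cell-binding simulator.** Two 25-cell populations carrying
  token pools of hypothetical adhesion genes bind through a dynamic
  cell–cell network: per step, bonds expire, the network is re-embedded
  with a force-directed layout, cells "speed date" (closer cells pair more
  often; 75% of pairs proceed), and molecule-level bonds form with
  lifetimes set by the gene pair (mismatched genes 1 step; same-gene
  3 × affinity-ratio steps). The in-silico coaggregation is the mean
  per-cell different-colour partner fraction after a 25% burn-in, averaged
  over 5 repeats, swept over affinity (1–10) and expression (1:1–20:1)
  ratios.
* **Mismatch-screen analytics.** Ordered-pair enumeration (n members →
  n(n−1) assays; 42 for 7), screen heat-map matrices, net mismatch scores
  score(X) = mean_Y (M[X,Y] − M[Y,X]) with ranking, and OLS regression of
  CoAg against the number of co-expressed members.
* **Synthetic data with ground truth** for every stage: seeded two-channel
  aggregate images at controlled mixing (segregated / interfaced /
  intermixed / single-colour / full-overlap), exact-area blob fixtures,
  nCounter-like count matrices with known per-cell on/off truth, qPCR Ct
  tables, and screen matrices with planted asymmetry.

## Worked example

```r
library(coaggr)

# a synthetic two-colour field of intermixed aggregates, and its CoAg
img <- make_aggregate_image(image_scenario("intermixed", seed = 1))$image
compute_coag(img)
#> CoAg = 0.4362 (41 of 94 occupied squares multicolour) -> intermix

# expression calling on a synthetic 27-gene x 50-cell panel
out   <- make_count_matrix(count_scenario(seed = 1))
calls <- call_expression(out$matrix,
                         panel = out$truth$scenario$target_panel)
summary(calls)
#> Calls on 27 genes x 50 cells (panel of 8 genes)
#>   per-cell expressed: max 6, mean 2.98; 20 fallback cell(s)
#>
#> 0 1 2 3 4 5 6
#> 7 8 6 8 7 7 7

# in-silico coaggregation of two identical 25-cell populations
pops <- list(population_spec("green", 25, c(A = 20)),
             population_spec("red",   25, c(A = 20)))
run_simulation(pops, gene_table("A", 1), sim_config(seed = 42))
#> In-silico coaggregation: 0.5146 (mean of 5 repeat(s): 0.504, 0.522, ...)
```

The CoAg value 0.4362 is the fraction of occupied grid squares containing
both colours — above 0.2, i.e. the two populations intermix, as planted.
The call summary closely recovers this seed's planted per-cell repertoire
(truth: max 6, mean 2.86 expressed panel genes per cell). The simulator's
0.5146 matches the analytic different-colour fraction 25/49 ≈ 0.510
expected when binding ignores colour.

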