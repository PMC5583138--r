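---
title: "Methods: retention ratios and wash-out dynamics in granular sludge reactors"
author: "washoutR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retention ratios and wash-out dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washoutR)
```

# The question and the statistic

Sequencing batch reactors selected for aerobic granulation impose strong
hydraulic selection: biomass that settles slowly leaves with the effluent.
Given paired 16S amplicon samples — granular biomass withdrawn from the
reactor and suspended solids collected from the effluent on the same day —
the **retention ratio** of a taxon is its relative read abundance in the
granular sample divided by its relative read abundance in the effluent
sample. A ratio of 1 means the taxon is washed out exactly in proportion to
its abundance; above 1, preferential retention; below 1, preferential loss.

Because both numerator and denominator are compositions, the ratio is
invariant to library size and to any joint rescaling of either compartment.
Two exact consequences are used as internal checks: with only two taxa, one
ratio above 1 forces the other below 1; and over a full table the
effluent-abundance-weighted sum of ratios equals 1.

# Analysis pipeline

1. **Phase assignment.** Days ≤ 42 (weeks 1–6) are start-up, later days
   steady state, reflecting when nitrogen removal typically stabilises. The
   boundary is a parameter (`startupEndDay`).
2. **Relative abundance** is computed per sample, never from pooled counts.
3. **Zero handling.** A taxon absent from an effluent sample has an
   undefined ratio. The default policy excludes such points, each flagged
   with a reason (`zero_effluent`, `zero_both`); nothing is interpolated or
   silently dropped. An optional pseudocount policy adds 0.5 reads to every
   cell before closure. Since closure renormalises each sample, the
   pseudocount shifts *all* ratios slightly, not only the undefined ones —
   the exclusion default is preferred for its transparency, and the counts
   of undefined points are always reported.
4. **Steady-state tests against 1.** A two-sided one-sample Wilcoxon
   signed-rank test per taxon and reactor. Zero differences are dropped
   before ranking; absolute differences receive midranks. For n ≤ 25 the
   p-value is exact: the null distribution of the positive-rank sum over
   all 2^n sign assignments is built by convolution over doubled midranks,
   which stays exact under ties (the base R test falls back to a normal
   approximation there, which is why the test is implemented in the
   package); beyond n = 25 a tie-corrected normal approximation with
   continuity correction is used. The test runs on the raw ratio scale; a
   log-scale option exists because the raw scale is asymmetric around 1
   (e.g. ratios 0.5 and 2.0 are not treated symmetrically — the package
   documents this with an explicit two-point example in its tests). A
   direction call (`above_1`/`below_1`) requires both p < 0.05 and the
   median on that side of 1.
5. **Temporal trends.** Pearson correlation of ratio against day over all
   defined points of both phases, p from the t transform on n − 2 degrees
   of freedom, significance stars at strict cutoffs (p = 0.05 earns `•`,
   not `*`). Series with < 3 defined points or zero variance are flagged
   `not_computable` instead of dropped. A Benjamini–Hochberg column is
   emitted alongside as a convenience; the stars follow the raw p-values.
6. **Community level.** Bray–Curtis dissimilarity is computed on per-sample
   relative abundances (library sizes differ systematically between
   compartments, so count-scale Bray–Curtis would conflate depth with
   composition). Paired similarity is (1 − BC) × 100 summarised per
   reactor; cross-reactor similarity averages all between-group sample
   pairs in a day window. Margalef richness (S − 1)/ln N and Pielou
   evenness H′/ln S are computed per sample.
7. **Dominant common genera.** "Common to all sample categories" is
   interpreted as nonzero mean relative abundance in every reactor ×
   compartment category (a configurable minimum-mean threshold defaults
   to 0); ranking uses the grand mean over all samples, with lexicographic
   tie-breaking for determinism, and a per-category-minimum ranking is
   available as an alternative. The cumulative share of the selection is
   reported with its across-sample standard deviation.

# NMDS

Ordination uses non-metric MDS minimising Kruskal stress-1,
sqrt(Σ(d − d̂)² / Σd²), alternating (a) weighted pool-adjacent-violators
isotonic regression of the configuration distances onto the rank order of
the input dissimilarities with **primary (weak) tie treatment** — tied
dissimilarities are ordered by their current configuration distances so
they do not constrain each other — and (b) a Guttman transform, with step
halving whenever a step would increase stress, so the per-iteration stress
trace is non-increasing by construction. The first start is the classical
scaling (metric MDS) configuration; the remaining starts (default 20 in
total) are uniform random, seed-controlled; the lowest final stress wins.
Convergence is a relative stress change below `tol = 1e-7` within
`maxIter = 300`. No abundance autotransform (Wisconsin/square-root) is
applied: the input is already a relative-abundance Bray–Curtis matrix, and
transforms can be applied upstream if wanted. Degenerate input with all
dissimilarities equal is flagged, not fatal. The isotonic-regression step
is validated against a brute-force minimax-formula fit, and whole
ordinations against an established independent implementation, in the test
suite.

# The wash-out simulator

The generator exists so that every stage above can be verified against
known ground truth. It encodes the minimal mechanism consistent with the
wash-out narrative: the effluent is an **erosion-biased sample** of the
reactor community, not an explicit particle model.

Deterministic daily dynamics for taxon fractions `p_i(t)`:

- granulation ramp `G(t)`: 0 before day 21, 1 after day 49, linear between
  (start-up biomass is flocculated and every floc settles alike; as
  granules develop, settleability differences emerge);
- enrichment `e_i(t) = exp(beta * (s_i − s̄(t)) * G(t))` where `s_i` ∈ [0,1]
  is surface affinity and `s̄` the abundance-weighted mean affinity —
  centring keeps the community-average enrichment near 1 so `beta` controls
  contrast rather than total wash-out;
- effluent composition `q_i = p_i e_i / Σ_j p_j e_j`; expected retention
  ratio `rho_i = p_i / q_i = Σ_j p_j e_j / e_i`;
- reactor update `p_i(t+1) ∝ p_i(t) exp(g_i − delta · e_i(t))` with net
  growth `g_i` and selective loss rate `delta`.

Observed counts are multinomial draws of `depth` reads per compartment at
each sampled day. The dynamics are seed-independent; the seed governs only
the noise, so different seeds share identical ground truth. Consequences
used as oracles: `beta = 0` (or `G = 0`) gives `q = p` and all expected
ratios exactly 1; fractions and the identity `Σ q_i rho_i = 1` hold to
1e-12; expected paired similarity decreases monotonically in `beta`.

**Default study conditions.** 3 reactors × 2 compartments × 13 sampled days
(3, 10, …, 80, 84 — a weekly cadence over a 12-week run plus the final day,
giving 6 start-up and 7 steady-state pairs per reactor; 78 samples in
total); 30 genera; depth 20 000 reads. The bundled scenario assigns the
three reactors erosion contrasts beta = 2.0, 1.5, 1.0 as a stand-in for
three loading regimes. Taxon parameters are deterministic: a geometric
abundance series (≈12-fold range), surface affinities on an even grid in
[0, 1] assigned by a fixed coprime permutation so affinity is not
confounded with abundance, growth rates in ±0.02 d⁻¹ by a second
permutation, and `delta = 0.03 d⁻¹` as a mild selective-loss rate. The
genus labels are illustrative of granular sludge communities (EPS formers,
denitrifiers, a predator, nitrifiers, three unclassified OTU placeholders)
and carry no taxon-specific parameter values.

**What the generator does not emulate:** overdispersion beyond multinomial
noise (real amplicon data are overdispersed; a Dirichlet-multinomial layer
would be the natural extension), granule breakage events, spatial structure
within granules, oxygen gradients, immigration, and primer or copy-number
bias. Tests passing on simulated data therefore demonstrate the
correctness and statistical behaviour of the pipeline under the stated
mechanism — not that real reactors obey it.

# Validation problem sizes

The test suite validates the statistics against independent oracles
(double-loop Bray–Curtis; full 2^n sign enumeration for the Wilcoxon test,
n ≤ 10; definitional Pearson formulas; minimax isotonic fits) and runs the
simulator-recovery studies at the default conditions: 50 replicate noise
seeds for Spearman recovery of steady-state ratios and for the sensitivity
of `below_1` calls on top-quartile surface taxa, and 540 neutral taxa
(18 replicates × 30 taxa at beta = 0) for the empirical type-I rate of the
exact test at nominal 0.05. With 7 steady-state pairs the exact two-sided
Wilcoxon can only reject at achievable levels 2/128 and 4/128, so the test
is conservative at this n.

# Known limitations

- Retention ratios are compositional ratios; they measure differential
  representation, not absolute growth or loss rates, and a high ratio can
  coexist with declining absolute abundance.
- Ratios at low counts are noisy and upward-biased (a ratio of noisy
  fractions); the exclusion zero-policy additionally censors the most
  extreme wash-out events (taxon absent from the effluent), which biases
  per-taxon summaries toward 1 for rare taxa.
- No multiple-testing correction is applied to the headline tables (the BH
  column is advisory); with ~19 genera × 3 reactors, a handful of nominal
  p < 0.05 calls are expected by chance.
- The time series are autocorrelated; the trend test treats points as
  independent, so its p-values are anti-conservative for strongly
  autocorrelated series.
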