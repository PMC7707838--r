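---
title: "Methods: bulk-segregant mapping of mRNA- and protein-QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulk-segregant mapping of mRNA- and protein-QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xqtl)
```

This vignette explains the statistical machinery of the package: the
generative model behind the synthetic cross, the hidden-frequency LOD
scan, the replicate-integration and false-discovery logic, and the
cross-channel classification — together with the numerical choices and
their rationale.

## The experimental design being modelled

A dual-reporter yeast strain reads out, in each live cell, the mRNA
production of a tagged gene (mCherry, driven through a gRNA released
from the transcript) and the abundance of its protein (GFP fusion).
Crossing a tagged BY strain to RM yields millions of recombinant
haploid segregants.  FACS collects the top and bottom ~3% tails of
each fluorescence channel (within a narrow cell-size gate), and pooled
whole-genome sequencing of each pool measures allele frequencies at
thousands of BY/RM markers.  A locus that raises expression drags its
BY or RM allele into the corresponding tail: the allele-frequency
difference between the high and low pool (ΔAF, always reported for
the BY/reference allele) is both the detection signal and the effect
size.  Because both channels are sorted from the same genetically
heterogeneous culture, mRNA-QTLs and protein-QTLs can be compared with
no environmental confounding.

## Synthetic cross (`simulate_segregants`, `simulate_phenotypes`)

Meiosis is a linear genetic map without crossover interference: the
first marker of each chromosome is Bernoulli(½) and the allele
switches between adjacent markers `d` bp apart with recombination
fraction `r = min(0.5, d / (bp_per_cM × 100))`, with 2,200 bp/cM (the
BY×RM map scale).  Segregants are i.i.d. — no tetrad structure and no
clonal expansion, which are second-order for pools drawn from large
spore populations.

Phenotypes are additive on the log-fluorescence scale.  Genotype 0
(BY) at marker *j* contributes `+a_j/2` to the latent transcription
value `t` and `+b_j/2` to the protein-specific value `s`; the observed
reporters are

```
R = t + γ·log(FSC) + ε_R            (mRNA reporter)
G = κ·t + s + γ·log(FSC) + ε_G      (protein reporter)
```

with log-normal cell size FSC.  The four locus classes are positions
in `(a, b)` space: concordant `(a, 0)`, protein-specific `(0, b)`,
mRNA-specific (perfectly buffered) `(a, −κa)`, and discordant
(over-buffered) `(a, b < −κa)`.  The default model plants one locus of
each class, 700 kb apart on two 1-Mb chromosomes, with |a| = 0.3 and
noise σ = 0.6 — via the truncation-selection formula in
`expected_delta_af()` this corresponds to an expected |ΔAF| ≈ 0.49 at
a 3% tail, i.e. a strong but realistic X-QTL.  The 700 kb separation
keeps the linkage flanks of same-channel loci from fusing into one
super-threshold run at these effect sizes (at 2,200 bp/cM the
inter-marker allele correlation decays to ~0.002 over 700 kb).

Sorting gates the central 60% of the FSC distribution, then takes the
`min(pool_size, ⌊q·n_gated⌋)` most extreme cells per tail (q = 0.03 by
default; reported X-QTL sorts used 3–5% tails and the default fixes
3%, overridable per experiment).  Sequencing draws per-marker depth
from Poisson(13) — the study's median coverage — and reference reads
from Binomial(n, p(1−e) + (1−p)e) with error rate e = 0.001.

What the simulator does **not** emulate: reporter maturation kinetics
and mCherry saturation, uneven marker density and segregation
distortion of the real cross, batch effects between sequencing runs,
and clonal structure in the pools.  Tests passing on simulated data
therefore validate the statistical machinery, not robustness to those
artefacts.

Under zero planted effects, a sorted tail is a uniformly random subset
of i.i.d. segregants, so `simulate_null_pools()` draws `2 × pool_size`
segregants directly and splits them — exactly the null distribution of
a full-scale sort at a fraction of the cost.  This is how pools of
10,000 (the FACS pool size) are simulated for null calibration without
generating the ≥550,000-segregant population a 3% tail would require.

## Allele-frequency tracks (`compute_af`, `filter_extreme`, `smooth_af`)

Frequencies are `ref/(ref+alt)` per marker, missing at zero depth.
Markers with a raw frequency above 0.9 or below 0.1 (strict
inequalities; boundary retained) in *either* pool of a pair are
removed from both before the scan — in a selected pool of a balanced
cross such values indicate unreliable markers.  Applying the filter
per pair rather than per pool keeps the two tracks on identical
marker sets; this is an assumption the source protocol leaves open.

Smoothing is a depth-weighted local-linear regression with tri-cube
weights inside a fixed **physical** bandwidth of 20 kb (half-width).
A physical bandwidth is robust to uneven marker density and sits well
below typical QTL support-interval widths; local-linear fitting is
exact on linear frequency gradients and leaves only curvature bias.
Smoothed values are clipped to [0, 1].  ΔAF for reporting is computed
on smoothed tracks; raw values are kept for diagnostics.

## The binned LOD scan (`lod_params`, `lod_track`)

The hidden BY allele frequency of a pool follows a Markov chain along
each chromosome.  Over a gap with recombination fraction `r` the
frequency moves to mean `p + r(1 − 2p)` (reversion toward ½) with
variance `r(1 − r)/N`, where N = 1,000 is the effective number of
independent segregants in a pool — for a pool of K independent cells
the true sampling variance of the frequency difference over a gap is
`r/K`, so N plays the role of K and 1,000 matches the study's setting.
Counts are summed into 100-bp bins; a bin with depth `n` and `k`
reference reads emits Binomial(k | n, p) (beta-binomial when the
overdispersion `rho > 0`).  The frequency grid has 201 uniform points
on [0, 1], resolving ΔAF of 0.01; the transition kernel is a
truncated-Gaussian discretization renormalized per row and computed in
log space so that tiny-variance kernels never underflow to zero rows.
Runs of empty bins are collapsed analytically: the chain steps
directly between informative bins with `r` computed from the full gap
(the linear map makes `r` additive in distance until the 0.5 cap).

The per-bin score contrasts "the two pools' latent frequencies are
equal at this bin" against independence.  With `P_h` and `P_l` the
smoothing posteriors of the two chains (forward–backward, scaled) and
π the uniform grid prior,

```
LOD(x) = −log10 [ Σ_v P_h(v|D_h) · P_l(v|D_l) / π(v) ]
```

is the log10 Bayes factor obtained by gluing the two otherwise
independent chains at bin x.  Because the posteriors pool information
across the whole linked region, evidence accumulates: at median 13×
depth the posterior SD of a local frequency is ~0.01–0.02, so a true
ΔAF of 0.4 yields LOD in the tens, while statistically identical pools
give overlapping posteriors and a Bayes factor near (or below) one.
Negative log-Bayes-factors carry no locational information and the
score is floored at 0, so "no contrast" reads as LOD ≈ 0.  The
forward–backward implementation is verified against brute-force
enumeration of all grid trajectories on ≤3-bin instances (tolerance
1e-6), and `hmm_posteriors()` exposes both the smoothing posteriors
and the leave-one-out predictives for diagnostics.

Thresholds follow the study: LOD ≥ 3.0 as a permissive candidate
threshold, LOD ≥ 4.5 (inclusive) for significance.  Null calibration
over unselected pool pairs (see `null_calibration_study()`) checks
that significant peaks are rare under the no-QTL null at these
settings.

## Peaks, replicates, FDR

`call_peaks()` reports one peak per maximal contiguous run of
informative bins at or above the threshold (no sub-peak splitting —
the 75-kb merge absorbs residual ambiguity; note that one-peak-per-run
calling is threshold-monotone only for unimodal profiles, which is why
the pipeline calls once permissively and then filters).  Support
intervals extend to the outer edge of the first bin 2 LOD units below
the peak, clamped at chromosome ends — a conservative interval.
Zero-depth bins carry no evidence and do not break runs.

`merge_replicates()` links same-chromosome peaks within 75 kb across
replicates.  Single-linkage closure is the default reading of "peaks
within 75 kb of each other" (a chain at 0 / 70 / 140 kb merges); a
strict-clique mode is provided for sensitivity analysis.  At every
member peak position the LOD and ΔAF are read from **every**
replicate's track — no per-replicate LOD filter — and averaged, then
averaged over members; positions and intervals are averaged over
members.  Reproducibility is summarized by
`fraction_overlap = mean[(NshareQTL − 1)/(Nrep − 1)]` over significant
merged QTLs of genes with ≥2 replicates.

The empirical FDR contrasts pools sorted into the same gate in
different replicates (same sequencing batch only): any peak there is a
false positive.  `FDR(thr) = (N_repQTL/N_rep)/(N_fluoQTL/N_fluo)`;
raw ratios above 1 are reported as computed, and a monotone
(running-minimum) version of the curve is also emitted because
empirical ratios at sparse thresholds are noisy.

## Concordance classification

Merged QTLs of the two channels (at the permissive threshold, after
removing peaks inside the chrXIV:350–550 kb region — inclusive bounds
— where a highly pleiotropic locus affects the mCherry reporter
independently of the tagged gene) are paired by confidence-interval
overlap within gene.  When one interval overlaps several partners the
highest-LOD partner wins (the closest-peak alternative is exposed);
six curation overrides matching the published analysis ship in
`curation_overrides()`.  Loci with at least one member at LOD ≥ 4.5
are kept — applying the stringent filter only after permissive pairing
deliberately retains pairs whose weaker member narrowly missed
significance, which is more conservative than declaring the stronger
member channel-specific.  Classes follow ΔAF signs; a both-member
locus with a ΔAF of exactly zero is flagged `NA`, never silently
assigned.  For specific loci, `effect_at_peak()` extracts the other
channel's smoothed ΔAF at the peak position, averaged across that
channel's replicate tracks, so effect-size and direction comparisons
(`direction_agreement()`, `effect_correlations()`) need no
significance in the other channel; the denominator of the direction
test is always reported.

## Problem sizes and reproducibility

The desk-scale default configuration — two 1-Mb chromosomes, 2,000
evenly spaced markers, 50,000 segregants, 2 replicates, 13× depth —
keeps a full simulated experiment plus mapping in the tens of seconds
while preserving the study's pool selectivity, marker spacing and
coverage.  The validation studies use 10 such experiments for
planted-QTL recovery and 50 unselected pool pairs (10,000 cells each)
for null calibration; `scripts/acceptance.R` re-runs both from a
single seed.  All simulation functions are deterministic given their
seed, and `run_simulate()` writes byte-identical datasets (counts as
TSV and VCF, truth tables, manifest, YAML config and provenance
record) across reruns.

## Known limitations

- The LOD model assumes binomial sequencing noise; real pools carry
  PCR-duplicate and mapping-bias overdispersion.  The `rho`
  (beta-binomial) knob exists but defaults to 0.
- The effective pool size N is a single genome-wide constant; regions
  of segregation distortion violate it.
- Merging and pairing are distance/overlap heuristics: two causal
  variants under one peak are reported as one locus, as in the source
  protocol.
- The classification inherits the thresholds' dichotomy; loci near
  LOD 4.5 can switch class between otherwise equivalent runs, which is
  why effect-extraction-based comparisons are also provided.
- Event tables are read from TSV; binary FCS containers are not
  parsed.
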