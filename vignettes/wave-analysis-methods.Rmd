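---
title: "Methods: the chromosomal mutation-rate wave analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chromosomal mutation-rate wave analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliwave)
```

## The problem

Mutation-accumulation (MA) experiments propagate many independent lines
of a microbe through repeated single-cell bottlenecks, so that almost
every mutation that arises is fixed regardless of fitness.  Sequencing
the endpoints gives per-line base-pair substitution (BPS) calls, and
dividing counts by generations gives rates.  In strains with inactive
mismatch repair the per-generation BPS rate varies several-fold along
the chromosome, forming a wave that is symmetric about the replication
origin.  This package implements the numerical pipeline that detects
and quantifies such a wave from a mutation table: circular binning,
rate estimation, wavelet smoothing, clockwise/counterclockwise wavelet
coherence, and region-stratified correlation tables — plus a synthetic
generator so the whole chain can be validated against ground truth.

## Coordinates and binning

A `genome_map` fixes the geometry: chromosome length $L$, origin
coordinate, and `n_bins` (default 46).  Positions are 1-based; offsets
are 0-based clockwise distances from the origin; bins are half-open in
offset space, bin $b$ covering $[(b-1)L/n,\; bL/n)$.  Two choices are
deliberate:

* **Bin width is exactly $L/n$, not a fixed 100 kb.**  With $n = 46$
  and the *E. coli* chromosome the width is ~100.9 kb; exact division
  guarantees the bins tile the circle with no remainder bin, so bin 46
  abuts bin 1 and circular operations (reversal, mirroring, periodized
  transforms) are well defined.
* **The floor is computed as `floor(offset * n / L)`**, which is exact
  in double-precision integer arithmetic, rather than dividing by the
  non-integer width.

The shipped default genome configuration (length 4,641,652 bp, OriC at
3,925,744) is the standard K-12 MG1655 annotation; it lives in a JSON
file, not in code, and any circular genome can be configured.  The
origin coordinate anchoring bin 1 and the exact-division rule are
package decisions — analyses that used fixed 100-kb bins will agree to
within one bin.

Region schemes follow the replichore layout at 46 bins: right
replichore bins 1–23, left 46–24, origin-proximal bins 1–13 and 46–34,
terminus-proximal 14–33.  For other (even) bin counts the origin arm
scales as 13/23 of a replichore.  The replichore pairing mirrors bin
$i$ onto bin $47-i$; note the origin sits at the *start* of bin 1, so
bin 1 pairs with bin 46.

## Rates and confidence limits

Rates are pooled — $\mu = \Sigma \mathrm{BPS} / \Sigma
\mathrm{generations}$, reported $\times 10^3$ — rather than means of
per-line rates; the pooled rate equals the generation-weighted mean of
per-line rates and reproduces published MA rate-table arithmetic
(e.g. 30,061 BPSs over 264,958 generations gives 113, and 1,933 over
2,015,066 gives 0.96).  Display rounding is whole numbers at or above
1 and two decimals below 1; internal values are full precision.

Because the among-line distribution of counts is not known a priori,
95% confidence limits use a nonparametric percentile bootstrap over
lines (default 10,000 replicates, seeded): lines are resampled with
replacement and the pooled rate recomputed.  A simulation in the test
suite checks that the interval covers a known true rate at roughly the
nominal level (≥ 93/100 seeded replicates at 40 lines).

## Wavelet smoothing

The smooth curve drawn over the per-bin rates is a Daubechies wavelet
smooth.  "Fourth-order Daubechies" is read as the filter with four
vanishing moments (8 taps); orders 1–6 are available.  Two transforms
are implemented:

* `dwt_periodic` / `idwt_periodic`: the decimated orthonormal
  periodized DWT.  It conserves energy and reconstructs exactly, but
  requires the length to be divisible by $2^{\mathrm{level}}$ — at 46
  bins only one level is possible.
* `wave_smooth`: the circular MODWT (maximal-overlap) multiresolution
  smooth, defined for any length and level.  The level-$J$ smooth
  retains periods longer than about $2^{J+1}$ bins, preserves the mean
  exactly, and is shift-covariant on the circle.

The default smoothing level is **2**: its pass band (periods ≳ 8 bins)
retains the dominant chromosome-scale wave (~12 bins per cycle) while
removing bin-to-bin noise.  Level 3 would pass only periods ≳ 16 bins
and visibly attenuates the wave itself — measured on a 46-bin grid it
removes 96% of the energy of a 12-bin cosine — so it is available but
not the default.

Periodized (circular) boundary handling is used for smoothing because
the chromosome is a circle.  The coherence analysis below instead uses
zero-padded, non-circular transforms with an explicit cone of
influence; this mirrors how such coherence plots are conventionally
computed and displayed, and the cone makes the edge-affected region
explicit rather than silently wrapping it.

## Morlet wavelet coherence

To test origin symmetry, the binned series is compared with itself read
counterclockwise ($y_i = x_{n+1-i}$).  Both are analyzed with the
analytic Morlet wavelet ($\omega_0 = 6$), scales on a dyadic grid with
12 voices per octave from 2 to 32 bins.  The magnitude-squared
coherence is

$$C(s,t) = \frac{|S(W_x \overline{W_y})|^2}{S(|W_x|^2)\, S(|W_y|^2)}$$

with $S$ a Gaussian smoother along positions (sd $0.6s$, kernel
renormalized near the edges so a constant field stays constant)
followed by a boxcar over 0.6 decades of scale.  Smoothing with
identical nonnegative weights in numerator and denominator bounds $C$
in $[0,1]$ by Cauchy–Schwarz.  The denominator is floored at
$10^{-12}$ times its peak — a relative floor, so identical inputs give
$C \equiv 1$ at every scale while scales with negligible energy cannot
divide by zero.  The phase of the smoothed cross-spectrum is the local
phase lag: 0 means in phase, $\pi$ means 180° out of phase, and with
this sign convention delaying $y$ by a quarter period yields
$+\pi/2$.

Scales convert to Fourier periods by $p = s\,4\pi/(\omega_0 +
\sqrt{2+\omega_0^2}) \approx 1.033\,s$, expressed as bins/cycle and,
via the bin width, kb/cycle; 12 bins/cycle ≈ 1,200 kb at the default
width.  The cone of influence uses the e-folding criterion: position
$t$ is trusted at scale $s$ iff $\min(t-1,\,n-t) \ge \sqrt{2}\,s$.  At
46 bins the largest fully-trusted scale is ~15.9 bins, so the usable
period range tops out near 16 bins/cycle — comfortably containing the
8–16 bins/cycle band where a symmetric ~1,200-kb wave produces its
coherence peak.

## Correlation tables and multiple testing

Pearson's product-moment $\rho$ is computed per region, with a
two-sided p-value from the exact t transform (a seeded permutation
option exists for small regions).  Because $\rho$ is invariant to
affine rescaling, correlating rates, counts or proportions of pooled
series is equivalent.  Perfect correlations give $p = 0$ exactly in
floating point; these are clamped to the smallest positive double so
downstream adjustment stays in its domain.

Benjamini–Hochberg adjustment is applied separately within each region
column (rows of a column share data, columns do not), and significance
is flagged at FDR 0.25.  One caution: BH adjustment is *not*
idempotent — re-adjusting already-adjusted values increases them — so
adjusted values are reported once and never re-fed to the procedure.

## The synthetic generator

`sim_spec` defines a relative intensity
$\lambda(x) = 1 + \sum_k a_k \cos(2\pi d(x)/p_k + \phi_k)$ (+ an
optional Gaussian terminus bump), where $d$ is the clockwise offset
from the origin, or the shorter-arc distance to the origin when
`symmetric = TRUE` (mirroring the wave across both replichores).
Construction rejects any spec whose intensity goes negative.  Per line,
totals are Poisson(generations × rate); positions are drawn from
$\lambda$ sampled on a 1-kb lattice (the intensity varies on the
≥ 100-kb scale, so the lattice is far below its resolution), then
uniformly within the chosen cell.  Duplicate positions are allowed and
counted separately, as in BPS tallies; there is no per-site
finite-sites correction, no selection, no lineage structure and no
sequencing-error model.  All randomness flows through one recorded
seed.

The `mmr_like_preset` encodes study-scale conditions scaled to a
desk-size experiment: 40 lines × 650 generations (26,000 total),
baseline 0.113 BPS/generation (the pooled MMR-deficient collective
rate, so the expected yield is ~3,000 mutations), a symmetric dominant
component of period 1,200 kb with amplitude 0.5 (≈ 3-fold
peak-to-trough), a weak 600-kb harmonic (amplitude 0.15), and a
terminus bump (height 0.8, sd 250 kb).  The amplitude follows the
observed 2–4-fold rate variation; the period sits mid-band in the
800–1,600 kb range where coherence is strongest.  These defaults are
the simulated study conditions, not tuning knobs.

With hot-spot enrichment configured, a synthetic i.i.d.-uniform
reference is generated (~1/8 of sites are 5′NAC3′/3′NTG5′ hot spots),
and A:T→G:C transitions are placed on hot-spot sites by rejection
sampling with the configured rate multiplier; ref/alt bases always
match the reference.  The synthetic reference does not reproduce the
real genome's base composition or site clustering, so tests exercising
it validate the classifier and filter logic, not genomic hot-spot
densities.

What passing tests on these data do and do not show: recovery of a
known symmetric cosine wave from Poisson-sampled positions demonstrates
that binning, coherence and the correlation tables behave correctly at
the study's signal-to-noise; it does not certify biological conclusions
about any particular strain, and real data add features the generator
omits (uneven coverage, calling errors, local context biases).

## Numerical choices and problem sizes

Daubechies filter coefficients are frozen constants (standard
extremal-phase values, sums $\sqrt{2}$, unit energy).  Transform
exactness is asserted at $10^{-9}$ relative $L_2$; mean preservation at
$10^{-6}$; coherence bounds at $10^{-9}$.  Bin assignment uses integer
products only.  Bootstrap and permutation procedures take explicit
seeds and restore the caller's RNG state.

The test suite validates stochastic claims at deliberately modest
sizes — 100 seeded replicates of the ~3,000-mutation preset for
symmetry recovery, 100 replicates at ~30,000 mutations for intensity
recovery, 10⁵ draws for sampler calibration — sizes chosen so the whole
suite runs in minutes on a laptop while keeping the binomial margins of
the pass criteria meaningful.

## Known limitations

* Single circular chromosomes only; no indels or multi-nucleotide
  variants.
* No significance testing of coherence against red-noise nulls; the
  coherence map is descriptive, with the correlation tables carrying
  the inferential weight.
* The decimated periodized DWT needs lengths divisible by
  $2^{\mathrm{level}}$; smoothing therefore goes through the MODWT.
* The bootstrap CL assumes lines are exchangeable; strongly unequal
  per-line generations are handled, but systematic line effects are
  not modeled.
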