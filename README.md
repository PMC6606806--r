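# repliwave

Wave analysis of base-pair substitution (BPS) rates along circular
bacterial chromosomes.

Mutation-accumulation (MA) experiments — repeated single-cell
bottlenecking of many independent lines followed by whole-genome
sequencing — measure mutation rates nearly free of selection.  In
mismatch-repair-deficient *E. coli*, the per-generation BPS rate is not
uniform along the chromosome: it rises and falls in a wave, symmetric
about the replication origin (OriC), with a dominant wavelength of
roughly 800–1,600 kb and elevated rates near the terminus.  `repliwave`
implements the analysis used to detect and quantify that pattern, for
anyone analyzing MA/WGS mutation tables from organisms with circular
chromosomes.

## What it computes

* **Origin-anchored circular binning.**  The chromosome is divided into
  `n` bins of exactly `L/n` bp (default 46, ~100.9 kb for *E. coli*),
  bin 1 starting at OriC and increasing clockwise.  A mutation at
  coordinate `x` falls in bin `⌊((x − ori) mod L) · n/L⌋ + 1`.
* **Rates.**  Pooled per-generation rates `μ = ΣBPS / Σgenerations`
  (reported ×10³) with nonparametric bootstrap 95% confidence limits
  over lines.
* **Daubechies smoothing.**  The smooth rate curve is the circular
  MODWT multiresolution smooth with the 8-tap Daubechies filter
  (4 vanishing moments); a decimated orthonormal periodized DWT
  (`dwt_periodic`) is also provided.
* **Wavelet coherence.**  Magnitude-squared Morlet wavelet coherence
  `C(s,t) = |S(Wx·W̄y)|² / (S(|Wx|²)·S(|Wy|²))` between the binned
  series read clockwise and counterclockwise, with phase arrows and a
  cone of influence — a symmetric wave makes the two directions
  coherent at the wave's scale.
* **Correlation tables.**  Pearson ρ between strains and a pooled
  reference, stratified by region (whole chromosome, right/left
  replichore, origin, terminus), and right-vs-left replichore ρ (bin
  `i` against bin `47−i`), with Benjamini–Hochberg adjustment per
  column at FDR 0.25.
* **Hot-spot filtering.**  Classification and removal of A:T→G:C
  transitions at 5′NAC3′/3′NTG5′ trinucleotide sites.
* **Synthetic MA data.**  A seeded generator with Poisson line totals
  and positions drawn from a configurable symmetric cosine-wave
  intensity, so every stage can be validated against ground truth.

## Worked example

```r
library(repliwave)

genome <- ecoli_genome()                       # 4,641,652 bp, OriC 3,925,744, 46 bins
spec   <- mmr_like_preset(genome, seed = 42)   # MMR-deficient-scale conditions
ds     <- simulate_experiment(spec)
#> <synthetic_dataset> 2992 mutations, 40 lines, 26,000 generations

series <- bin_mutations(ds$records, genome, ds$meta)
round_rate(genome_rate(nrow(ds$records), ds$meta$total_generations))
#> [1] 115          # BPS per generation x 10^3 (preset truth: 113)

cm   <- wavelet_coherence(series$rates, ccw_series(series)$rates)
prof <- coherence_profile(cm)
prof$period[which.max(prof$mean_coherence)]
#> [1] 15.6         # bins/cycle ~ 1,574 kb/cycle: inside the 800-1,600 kb band

replichore_table(series, genome)
#>      strain   region   rho    p_raw    p_adj n_bins significant_at_fdr
#> 1 synthetic    whole 0.932 1.03e-10 1.03e-10     23               TRUE
#> 2 synthetic   origin 0.923 6.67e-06 6.67e-06     13               TRUE
#> 3 synthetic terminus 0.956 1.61e-05 1.61e-05     10               TRUE
```

The pooled rate recovers the configured 0.113 BPS/generation; the
clockwise/counterclockwise coherence peaks at ~16 bins/cycle, and the
right replichore mirrors the left with ρ > 0.9 — the signatures of an
origin-symmetric rate wave.

`run_pipeline()` chains these stages and writes TSV tables plus a JSON
manifest; `inst/cli/repliwave.R` exposes them as shell subcommands
(`simulate`, `bin`, `smooth`, `coherence`, `compare`, `run`).

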