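# alleloop

Quantitative single-allele analysis of chromatin looping and optogenetic
protein clustering from high-throughput imaging tables.

## What it does, and for whom

Optogenetic looping experiments tether a light-clustering photoreceptor
(e.g. CRY2 fused to dCas9) to two genomic loci and ask whether blue light
pulls the loci together — and whether the induced contact represses the
gene. The raw evidence is imaging: dual-colour DNA-FISH spots mark the two
loci on every allele, RNA-FISH spots mark active transcription sites, and
masked nuclear images report protein clustering. `alleloop` is for
researchers who have the segmented output of such experiments (per-nucleus
and per-spot tables, nuclear-stain images) and need the downstream
quantification:

* **Clustering metrics** — the coefficient of variation (CV) of masked
  nuclear intensity, CV = σ/μ over nucleus pixels, as the clustering
  statistic; half-maximal clustering and declustering times t_c / t_d by
  linear interpolation of CV time series; logistic fits of CV versus
  expression level.
* **Registration** — per-field integer-pixel translation between
  sequential imaging rounds by Fourier phase correlation of the
  nuclear-stain images, propagated to spot coordinates.
* **Contact quantification** — nucleus QC (area ≥ 90 µm² U2OS / 50 µm²
  HeLa, solidity ≥ 0.9), ploidy filtering (spot count per DNA channel must
  equal the allele number), greedy one-to-one cross-channel spot matching
  capped at 2 µm, contact calling at distance < 0.27 µm, per-cell
  transcription-site summaries, and equal-count binning (cells with zero
  close alleles form their own bin "0").
* **Allele statistics** — under allele independence the number of close
  alleles per cell is binomial,
  f(c) = C(n,c) · p_c^c · (1 − p_c)^(n−c), with p_c the population
  close-allele frequency and n the ploidy; the package compares observed
  per-cell distributions against this null with a Pearson chi-square test,
  and compares contact fractions across conditions with the Marascuilo
  multiple-proportion procedure.
* **Synthetic data** — a generator producing nucleus/spot tables, cluster
  images, registration fixtures and kinetic traces with known ground
  truth (controlled contact probability, allele coupling via a
  beta-binomial hierarchy, expression-dependent looping, spot dropout and
  false spots, contact-dependent transcriptional repression), used by the
  test suite to exercise every stage end to end.

## Worked example

```r
library(alleloop)

cfg <- list(
  simulate = list(
    dark  = list(n_cells = 2000, p_loop = 0.10),
    light = list(n_cells = 2000, p_loop = 0.40, allele_coupling = 0.3,
                 rna_p_on = 0.4, repression_effect = 0.6)
  ),
  analysis = list(ploidy = 2, n_bins = 3),
  seed = 42
)
res <- run_pipeline(cfg, out_dir = "run1")
res$stats$contact_fractions
#>   condition fraction_close n_alleles
#> 1      dark      0.1835369      3438
#> 2     light      0.4593578      3457
res$stats$independence
#>   condition    N       p_c       chi2 df      p_value stars
#> 1      dark 1710 0.1842105  0.1008728  1 7.507847e-01    ns
#> 2     light 1723 0.4599536 83.9782429  1 5.002499e-20   ***
res$stats$marascuilo
#>   group_i group_j       p_i       p_j  abs_diff critical_range significant
#> 1    dark   light 0.1835369 0.4593578 0.2758209     0.02105716        TRUE
```

The dark condition (loop probability 0.10) shows ~18% of alleles in
contact — the free-distance law alone puts ~9% of unlooped pairs below the
0.27 µm threshold — while the light condition (loop probability 0.40)
shows ~46%; the Marascuilo table confirms the difference exceeds its
critical range. The chi-square column tests each observed distribution of
cells with 0/1/2 close alleles against the binomial expectation at the
pooled p_c: the dark alleles are independent and compatible with the null,
while the light condition (generated with intra-cell allele coupling 0.3)
deviates strongly. The `report.txt` written to `run1/` contains the same
numbers plus median distances and binned RNA metrics; `manifest.json`
records per-stage nucleus counts and the config for exact reruns.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `sim_config()`, `generate_fish_dataset()`, `simulate_close_allele_counts()`, `generate_kinetic_trace()`, `generate_cluster_image()`, `generate_image_pair()` |
| Clustering | `compute_cv()`, `relative_cv_series()`, `estimate_tc()`, `estimate_td()`, `fit_cv_expression()` |
| Registration | `phase_correlation()`, `apply_translation()` |
| Quantification | `analysis_config()`, `qc_filter_nuclei()`, `ploidy_filter()`, `match_spots()`, `call_contacts()`, `summarize_cells()`, `bin_cells()`, `condition_contact_fraction()`, `median_pair_distance()` |
| Statistics | `binomial_expected()`, `observed_distribution()`, `independence_test()`, `marascuilo()`, `p_stars()` |
| Orchestration | `run_pipeline()`, `pipeline_report()` |

See the methods vignette
(`vignettes/single-allele-contact-analysis.Rmd`) for the statistical
model, numerical choices and known limitations.
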