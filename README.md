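# gwrsig

Spatial interaction signatures for two-type cell point patterns, with
pairwise disease-group classification.

## What it does, and for whom

Pathology images phenotyped by multiplex immunofluorescence reduce to
tables of cell centroids labelled *epithelial* / *immune* / *other*. For
several pancreatic diseases (chronic pancreatitis, ductal adenocarcinoma,
cystic precursor lesions) the groups differ less in how many immune cells
are present than in *where* they sit relative to the epithelium. `gwrsig`
is for computational pathology and spatial-statistics researchers who want
a per-image, spatially resolved summary of that relationship and a
classifier built on it.

The chain: per-phenotype edge-corrected Gaussian kernel intensity surfaces
`λ̂(u) = e(u) Σᵢ k(xᵢ − u) wᵢ`; a geographically weighted regression of
immune on epithelial intensity over the grid region where `λ̂_epi > τ`,
with adaptive bisquare weights and the neighbour count chosen by the
corrected AIC, `AICc = 2n log σ̂ + n log 2π + n (n + tr S)/(n − 2 − tr S)`;
the local-slope field `β₁(u)` min-max scaled cohort-wide and summarised as
a kernel density on [0, 1] — the image's (or subject's) *signature*;
Fisher–Rao geometry on square-root densities (`d = arccos ∫√(f₁f₂)`,
Karcher mean, tangent PCA at the 99.99%-variance rule); and a probit
classifier on the PC scores under leave-one-out cross-validation with
AUC, DeLong 95% CI, Youden sensitivity/specificity, a 0.75-AUC
significance flag and Bonferroni-corrected DeLong p-values across all
group pairs. The quadrat-based Morisita–Horn index
`MH = 2Σ e_q i_q / ((Σe_q²/E² + Σi_q²/I²) E I)` is the abundance baseline.

Because cohorts of this kind are institutional, the package includes a
seeded generator of synthetic cohorts whose immune process follows a
controllable spatially varying coupling `b(u)` — the ground truth the GWR
slope field recovers.

## Worked example

```r
library(gwrsig)

pa <- group_sim_params(coupling = coupling_constant(0.5), noise_sd = 0.15)
pb <- group_sim_params(coupling = coupling_patchwise(matrix(c(0, 3), 1, 2)),
                       noise_sd = 0.15)
cells <- simulate_cohort(list(A = pa, B = pb), c(A = 15, B = 15),
                         images_per_subject = 2, seed = 1)

cfg <- pipeline_config(grid_n = 24, level = "image",
                       window = obs_window(0, 600, 0, 600))
res <- run_pipeline(cells, cfg)
print(res$results, width = 100)
#> # A tibble: 1 × 13
#>   group_1 group_2 level   n_1   n_2   auc ci_low ci_high sensitivity specificity
#>   <chr>   <chr>   <chr> <int> <int> <dbl>  <dbl>   <dbl>       <dbl>       <dbl>
#> 1 A       B       image    30    30     1      1       1           1           1
#>   p_value p_adj significant
#>     <dbl> <dbl> <lgl>      
#> 1       0     0 TRUE
```

Group A couples immune to epithelial intensity uniformly (slope 0.5);
group B has two spatial regimes (slopes 0 and 3). Their slope-density
signatures differ in shape (unimodal vs bimodal), and the image-level
LOOCV probit separates the 30 image signatures per group perfectly
(AUC 1.0; `significant = TRUE` at the 0.75 flag). `autoplot(res$signatures)` draws the per-image signatures
by group; `plot_principal_path()` shows ±2 SD of a group's first principal
mode around its Karcher mean. Refitting with both groups from one
generator gives AUC ≈ 0.5, the expected null.

## Layout

- `R/` — implementation (cells I/O, synthetic cohorts, intensity, GWR,
  signatures, Fisher–Rao geometry, classification, Morisita–Horn,
  pipeline).
- `tests/testthat/` — unit, property and end-to-end suites; all fixtures
  are generated in code.
- `vignettes/interaction-signatures.Rmd` — the methods vignette: model,
  assumptions, parameter meanings, numerical choices, generator design,
  limitations.
- `inst/cli/gwrsig.R` — thin command-line wrapper
  (`simulate` / `classify-all` / `mh`).
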