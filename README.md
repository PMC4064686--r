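# placodyn

Quantitative analysis of pulsatile medial-myosin dynamics and apical
constriction in epithelial placodes, from two-channel confocal time-lapse
z-stacks (membrane marker + myosin reporter).

During tube invagination, placodal cells constrict their apices in pulses: a
medial actomyosin network flares with a cycle length of roughly 120–180 s,
each flare driving a constriction pulse of which part is retained (a
ratchet), and the phase of medial myosin runs ahead of the inverse apical
cell radius by a fraction of a cycle. Turning raw movies into those numbers
takes a long image-analysis chain, and this package implements all of it for
R users working on epithelial morphogenesis:

- **Surface extraction**: the curved apical surface is fitted per frame as a
  smooth "blanket" over the cortical signal (per-column optimum + Lipschitz
  smoothness bound), and quasi-2D images are maximum-projected from a
  1–1.5 µm layer beneath it.
- **Segmentation & tracking**: adaptive (block-normalized) seeded watershed
  with hierarchical basin merging; greedy maximal-overlap linking; QC rules
  for size, relative speed to neighbors, area-change rate, lineage length,
  and field-of-view contact.
- **Fluctuation analysis**: medial/junctional intensity partitioning with
  baseline subtraction; boxcar detrending (6 min window); trough-to-trough
  (myosin) and peak-to-peak (radius) cycle detection; activity = amplitude ×
  frequency classified against thresholds (0.5 for myosin, 0.005 for
  radius); pooled fluctuation fractions; phase-binned averages with 95% CIs
  and the myosin-over-inverse-radius lead in cycles.
- **Spatial statistics**: per-cell neighbor dispersion of apical areas,
  pit-centered radial profiles (5 µm bins, 1.96 SEM CIs), windowed
  area-change rates.
- **Tests named in this literature**: two-sample Kolmogorov–Smirnov,
  G test of independence, Student/Welch t.
- **Synthetic placode generator**: Voronoi epithelium on a shared-vertex
  mesh, per-cell raised-cosine myosin oscillations with a configurable
  radius lag, ratcheted constriction, radial activity gradient, curved
  surface, PSF + Poisson noise rendering — with full ground truth, so every
  stage of the pipeline is verifiable end to end without any microscope.

## Worked example

Simulate the default scene — 150 cells on an 80 × 80 µm field, 15 min at
20 s frames, mean myosin period 150 s, inverse radius trailing myosin by
0.125 cycles — then run the complete analysis chain on the rendered movie:

```r
library(placodyn)

mov <- default_movie(seed = 1)      # simulate + render (two-channel 5D stack)
an  <- run_placode_pipeline(mov)    # project -> segment -> track -> analyze
an
#> placode_analysis
#>   instances analyzed: 4363 (of 6776 tracked)
#>   myosin-fluctuating: 69%; radius|myosin: 84%
#>   mean myosin cycle length: 154 s; myosin lead: 0.120 cycles
```

Reading the output: of 6,776 tracked cell instances, 4,363 passed QC and
carried analyzable traces; 69% of those fell inside myosin fluctuation
cycles with activity ≥ 0.5. The measured mean cycle length (154 s) recovers
the generating 150 s period to within one frame interval, and the estimated
phase lead of myosin over the inverse apical radius (0.120 cycles) recovers
the imposed 0.125 — the "myosin runs an eighth of a cycle ahead" signature.

The same fraction arithmetic applied to published pooled counts (1,849
myosin-fluctuating of 2,877 wild-type instances vs 1,584 of 3,711
microtubule-depleted ones) gives 64% vs 43%, with `g_test()` on the 2 × 2
table yielding G = 305.6, p ≈ 2 × 10⁻⁶⁸:

```r
fluctuation_fractions(counts = list(total = 2877, myosin = 1849, both = 929))$pct_myosin_fluct
#> [1] 64.26834
g_test(matrix(c(1849, 1028, 1584, 2127), nrow = 2, byrow = TRUE))$p_value
#> [1] 2.006617e-68
```

The numbered scripts under `analysis/` run the full study as a narrative:
`01_simulate.R` (scenes + ground truth), `02_project_segment.R` (surface,
segmentation, tracking, accuracy vs truth), `03_fluctuation.R` (cycles,
fractions, phase lead), `04_spatial_stats.R` (dispersion, KS, radial
profiles). Each writes its tables under `results/`.

## Package layout

- `R/` — implementation: epithelium/dynamics/rendering (synthetic data),
  surface + projection, segmentation + tracking + QC, geometry and spatial
  metrics, fluctuation analysis, statistical tests, pipeline driver, TIFF/CSV
  I/O.
- `analysis/` — the numbered study drivers described above.
- `vignettes/placodyn-methods.Rmd` — the model, every tunable parameter with
  units and defaults, numerical conventions, and known limitations.
- `tests/testthat/` — unit, property and end-to-end recovery suites
  (fixtures are generated in code; no binary data).
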