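# myodyn

Morphodynamics and dynamic transcriptomics of myogenic differentiation.

FSHD (facioscapulohumeral muscular dystrophy) myoblasts differentiate into
hypotrophic myotubes: they align and fuse more slowly than matched healthy
myoblasts and never reach normal size. `myodyn` implements the computational
chain that characterises this, from raw measurements to ranked gene lists:

1. **Image quantification** — marker-positive (MyHC) area fraction from
   immunofluorescence fields; per-cell eccentricity
   (`sqrt(1 - (minor/major)^2)` of the second-moment ellipse) from
   phase-contrast time-lapse frames, averaged per field.
2. **Morphodynamics** — polynomial fits of each line's mean-eccentricity
   time course; empirical-Bayes moderated-t tests of per-time-point
   differences between lines; turning points of the fitted curves; and the
   *nodal time points* (union of both lines' turning points plus endpoints)
   at which transcriptomes are sampled.
3. **Dynamic differential expression** — median-of-ratios size factors, the
   per-gene interaction regression

   `E_i = a_i FSHD_status + b_i Time_differentiation + c_i (FSHD_status : Time_differentiation)`

   on log2-normalised counts (intercept included by default), one-sided
   coefficient tests, top-500 gene lists per coefficient and sign, Fisher's
   exact gene-set over-representation, and the validation statistics
   (signature-mean t-test; within-pair z-normalisation + unpaired Wilcoxon).
4. **Synthetic data** — generators for microscopy fields, time-lapse
   eccentricity series and negative-binomial count matrices with recorded
   ground truth, used by the test suite to validate every stage end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # traces, demo frames, counts, gene sets
Rscript analysis/02_image_quant.R     # area + eccentricity quantification
Rscript analysis/03_morphodynamics.R  # fits, differential ecc, nodal times
Rscript analysis/04_dynamic_de.R      # regression, ranking, enrichment
```

`01` simulates 1440 frames per well (8640 in total) for two lines in
triplicate, plus three sequencing batches of 48 + 24 + 18 = 90 samples.
`02` recovers the rendered ground truth (mean-eccentricity error 0.006 over
160 demo frames; hypotrophic vs control area `t = 17.9, p = 5.8e-05`).
`03` prints the fitted turning points and the nodal list:

```
== control ==
poly_fit: degree 6 over [0, 2880] min (577 points, RMSE 0.011)
turning points:
  time_min type
  439.1173  max
 1350.6702  min
 1863.3517  max
...
nodal time points (min): 0, 439, 531, 1351, 1512, 1863, 2168, 5040
```

`04` fits 10,000 genes in the 48-sample design and finds the planted
"suppressed in diseased differentiation" set only where it should be:

```
c_negative   top set: PGC1A_TARGETS_SYN  overlap  70/100  BH p = 1.07e-67
signature mean, 16Abic vs 16Ubic myotubes: t = 255.05, p = 6.34e-06
top suppressed gene gene05878, myotubes, paired-z Wilcoxon p = 0.00216
```

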