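# strandfold

Strand-resolved chromatin replication analytics for R.

During DNA replication, histone chaperones such as CAF-1 deposit new H3–H4
onto the daughter strands behind the fork, guided by the PCNA sliding
clamp. Several complementary assays quantify this process, and `strandfold`
implements their analysis layer as one tested toolkit:

* **SCAR-seq strand partition** — from per-bin forward/reverse read counts
  of nascent-chromatin pulldowns, compute the partition score
  `(F − R)/(F + R)` (and the Okazaki-fragment RFD convention
  `(R − F)/(F + R)`), with CPM normalization, ±30-bin uniform smoothing,
  input subtraction with zero clipping, a 0.3-CPM coverage filter,
  initiation-zone meta-profiles, and dm6-style spike-in normalization.
* **NAQ-seq plasmid pipeline** — for nucleosome assembly & quantitation
  libraries on a nicked (clamp-loaded) versus supercoiled plasmid pair:
  dual-index demultiplexing (index required on both mates), 5′ index
  trimming, unique-best mapping to small circular references, 125–160 bp
  mononucleosome fragment selection, percent-nicked and
  loading-control-normalized coverage.
* **Gel densitometry** — minimum-profile background subtraction, λ/HindIII
  ladder calibration (`log10(bp) = slope·Rf + intercept`), product-front
  detection, maximum replication rate as the OLS slope of front size over
  the earliest three chase timepoints (kb/min), EMSA percent-bound, and
  full-length-product fractions.
* **Binding fits** — one-site Hill fits
  `response = baseline + amplitude·c^h/(Kd^h + c^h)` for EMSA titrations
  (Hill slope free or constrained), one-site fluorescence-polarization
  fits, with multi-start Levenberg–Marquardt optimisation.
* **Mass photometry** — contrast calibration against protein standards,
  shared-σ Gaussian-mixture peak fitting, and assignment of peak masses to
  chaperone/clamp stoichiometries by exhaustive enumeration.

Every stage has a synthetic-data generator with known ground truth
(`gen_references`, `sim_naq_readpairs`, `sim_scar_samples`, `sim_gel_lane`,
`sim_titration`, `sim_mass_events`), so the whole package is validated by
parameter recovery. See the methods vignette
(`vignettes/strandfold-methods.Rmd`) for the models, assumptions and
numerical choices.

## Worked example

Simulate a NAQ-seq library in which half the nucleosomes assemble on the
nicked plasmid, and run the full read pipeline:

```r
library(strandfold)

refs  <- gen_references(seed = 1)                 # nicked / supercoiled / control
truth <- naq_sim_truth(p_nicked = 0.5, n_pairs = 2000,
                       index = "ACGTTGCA", seed = 42)
pairs <- sim_naq_readpairs(truth, refs)
naq_pipeline(pairs, refs, index_table(c(rep1 = "ACGTTGCA")))
#>   sample n_pairs n_mapped n_selected n_control percent_nicked
#> 1   rep1    2000     2000       1833        97        48.3871
```

All 2000 pairs demultiplex and map; 1833 fragments survive the 125–160 bp
selection, 97 of them on the loading control. The recovered
`percent_nicked` of 48.4% sits within binomial sampling error of the 50%
ground truth (SE ≈ 1.2 points at this depth).

Fit a noisy EMSA titration generated at Kd = 0.33 µM:

```r
cv <- sim_titration("one_site_hill",
                    list(Kd = 0.33, h = 1, amplitude = 100, baseline = 0),
                    10^seq(log10(0.01), log10(5), length.out = 10),
                    noise_sd = 0.05, noise_model = "proportional", seed = 7)
fit_one_site_hill(cv)
#> BindingFit: Kd = 0.4622, hill = 0.855, amplitude = 116.9, baseline = -1.88
#>   rss = 38.71, converged = TRUE
```

A single noisy 10-point curve constrains Kd only loosely (this seed lands
40% high); across 100 seeds the median relative error is about 8%, which
is what the test suite asserts.

Replication rate from gel fronts at chase timepoints 4, 5, 6 min:

```r
est <- max_replication_rate(c(`4` = 1880, `5` = 2970, `6` = 4060))
est
#> RateEstimate: 1.090 kb/min (3 points, RMS 3.2e-16 kb)
normalize_rate(0.85, est$rate)
#> [1] 0.7798165
```

A command-line interface wrapping the same functions is installed at
`system.file("exec/strandfold", package = "strandfold")`, with subcommands
`simulate`, `scar`, `naq`, `gel` and `fit`.

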