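---
title: "strandfold: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strandfold: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandfold)
```

# Scope

`strandfold` implements the quantitative analysis layer of a set of
replication-coupled chromatin assembly experiments: strand-resolved
sequencing of nascent chromatin (SCAR-seq style), a plasmid-based nucleosome
assembly and quantitation (NAQ) MNase-seq readout, gel densitometry for
replication rates and band quantification, equilibrium binding-curve fits,
and mass-photometry peak analysis. Every analysis stage is paired with a
synthetic-data generator that produces inputs with known ground truth, so
the package is validated end to end by parameter recovery rather than by
comparison to any external dataset.

# Strand partition analysis

Strand-resolved ChIP of nascent chromatin yields, per genomic bin, read
counts on the forward (`F`) and reverse (`R`) strand for a pulldown and a
matched input library. The pipeline is, in order:

1. **CPM normalization** — each strand is scaled by `1e6 / library_total`,
   where the denominator is the library's total mapped target-genome reads
   (one library is strand-split after sequencing, so both strands share the
   denominator).
2. **Uniform blur** — each bin is replaced by the mean of the 30 bins on
   either side. Edge windows are truncated to the track and renormalized by
   their actual size; padding would fabricate signal beyond chromosome ends.
3. **Input correction** — the smoothed input CPM is subtracted per strand
   and negative values are clipped to zero. The input is smoothed the same
   way before subtraction; subtracting an unsmoothed track would mix
   scales.
4. **Coverage filter** — bins where *both* strands fall below 0.3 CPM are
   masked. We read the filter as a joint-low-coverage rule rather than
   "either strand below": a bin with strong one-sided signal is exactly
   what maximal strand asymmetry looks like, and discarding it would bias
   the partition toward zero. The comparison is strict (`<`).
5. **Partition** — `(F − R) / (F + R)` on kept bins; zero-total bins are
   undefined. The replication-fork directionality (RFD) convention used for
   Okazaki-fragment data is the exact negative, `(R − F) / (F + R)`, and is
   computed from the same code path so the identity `rfd = -partition`
   holds bin for bin.

Meta-profiles around initiation zones average the partition at each signed
offset; zones whose RFD transition points the other way (orientation −1)
are mirrored *and* sign-flipped, so leading-strand bias accumulates on a
consistent side of the averaged curve.

Spike-in normalization expresses each sample's target-genome total relative
to its exogenous spike-in count, then relative to a designated reference
sample, making total-abundance changes comparable across libraries.

## What the SCAR generator emulates

`sim_scar_samples()` draws per-bin Poisson counts whose forward-strand
fraction at signed offset `d` bins from the nearest initiation zone is
`0.5 * (1 + a * s(d))` with `s(d) = sign(d) * exp(-|d| / decay_bins)`. The
odd-symmetric exponential is a modelling choice: it has the right
qualitative shape (antisymmetric, decaying away from the zone) and a single
scale parameter. The default `decay_bins = 300` (300 kb at 1 kb bins)
reflects the hundreds-of-kilobase scale over which strand bias relaxes
around mammalian initiation zones; it also keeps the ±30-bin blur a mild
perturbation of the profile rather than a major attenuation (a boxcar of
width 61 attenuates the exponential peak by `exp(-30/300) ≈ 0.90`).

One generator parameter deserves explanation: `enrichment` (default 10).
CPM normalization forces any two tracks covering the same bins to the same
mean, so if the simulated input covered only the simulated region,
input subtraction would annihilate the below-average strand in every bin
and drive the partition to ±1 everywhere. In a real experiment the
pulldown concentrates its library into enriched regions while the input
spreads genome-wide, so the local input CPM is several-fold lower than the
pulldown's. The generator models exactly that: the input's *library total*
is `enrichment ×` its in-region reads, as if the rest of the library
mapped elsewhere in the genome. Input correction then removes a
`1/enrichment` pedestal, which mildly rescales the partition by
`1/(1 − 1/enrichment)` (+11% at the default); together with the blur
attenuation (×0.90) the recovered meta-profile extremum for an injected
amplitude of 0.4 is ≈ 0.40, which is what the recovery tests measure.

The generator does **not** model: sequencing errors, PCR duplicates,
mappability structure, nucleosome positioning, copy-number variation, or
replication-timing covariates. Passing recovery tests therefore
demonstrate the correctness of the arithmetic pipeline, not robustness to
those real-data artefacts.

# NAQ-seq read pipeline

The NAQ assay distinguishes clamp-dependent nucleosome assembly (on a
nicked, clamp-loaded plasmid) from clamp-independent assembly (on a
supercoiled plasmid in the same tube), with a short linear amplicon as
loading control. Libraries are MNase digests; both mates of each pair
carry a ligated sample index at the 5′ end.

* **Demultiplexing** requires the index on *both* mates (default 0
  mismatches; the index-table invariant of pairwise distance ≥ 2 keeps
  single-mismatch assignment unambiguous). Pairs matching no sample, or
  two different samples, are discarded.
* **Mapping** uses an exact 31-mer seed from the read 5′ end against a
  hash of all reference k-mers (circular molecules are doubled so
  origin-spanning reads map), followed by full ungapped verification. A
  mate maps only when exactly one reference location matches; a fragment
  is emitted only when both mates map uniquely to the same reference in
  convergent orientation. Unique-best-hit replaces an aligner MAPQ
  threshold; at plasmid scale, with references generated k-mer-disjoint, a
  full aligner would add nothing for error-free reads. The test suite
  checks the mapper against a literal all-rotations, all-positions scan.
* **Fragment-length selection** keeps the closed interval 125–160 bp, the
  mononucleosome-protected size range.
* **Percent nicked** is `100 · n_nicked / (n_nicked + n_supercoiled)`,
  loading-control fragments excluded from both numerator and denominator.

The read generator places fragments uniformly (MNase products carry no
positioning model), draws lengths from Normal(145, 10) truncated to
[50, 250] bp — a stand-in centred in the selection window, since the true
library length distribution is not otherwise constrained — and reads 75 nt
of insert per mate after the index, truncated for shorter inserts.

# Gel densitometry

Lanes are one-dimensional position→intensity vectors (image→lane
extraction is out of scope).

* **Background** is the lower envelope of the lane: a running minimum over
  a window defaulting to 1/10 of the lane, subtracted and clamped at zero.
* **Ladder calibration** fits `log10(size) = slope · Rf + intercept` by
  least squares on ≥ 3 bands, with the retardation factor `Rf` defined as
  migration position over the full lane span (the reference point is a
  package choice; only the composition `position → size` matters
  downstream).
* **Front detection** locates the high-molecular-weight edge of a product
  smear as the first position (scanning from the least-migrated side)
  where intensity exceeds 5% of the lane maximum, linearly interpolated
  between samples. The threshold is relative, so exposure cancels. Two
  numerical choices matter: the 5% level is a surrogate for a commercial
  package's undocumented band-edge rule (sensitivity: on the synthetic
  ramp-edged lanes used in the tests, the detected *size* changes by under
  2% when the threshold varies between 2% and 10%, because the edge is
  steep); and the crossing must be sustained for 5 consecutive positions,
  so isolated noise specks upstream of the band cannot masquerade as the
  front.
* **Maximum replication rate** is the OLS slope of front size (bp) versus
  chase time over the earliest three timepoints, reported in kb/min, with
  normalization of each condition to a designated reference reaction.
* **EMSA percent bound** is inferred from depletion of the unbound band:
  `100 − 100 · unbound / unbound_reference`, clamped to [0, 100].

The lane simulator builds a linear front ramp (5% crossing placed exactly
at the requested size's migration position, so noiseless recovery is
analytically exact), a flat plateau, and an exponential smear toward
smaller products; the ladder lane comes from the same calibration.

# Binding curves

EMSA titrations are fit to the one-site Hill model
`response = baseline + amplitude · c^h / (Kd^h + c^h)` by
Levenberg–Marquardt least squares. Initialisation is multi-start — Kd at
the concentration nearest half-maximal response and at geometric quartiles
of the concentration range, `h ∈ {0.5, 1, 2}` — and the best residual sum
of squares wins; bounds keep `Kd` and `h` positive. The Hill coefficient
can be constrained (e.g. to 1) where the experiment calls for it.
Fluorescence-polarization curves use the same machinery with `h = 1`;
`baseline` is the free-probe polarization and `amplitude` the bound–free
difference. Amplitudes float rather than being pinned to a 100% plateau,
since saturation of the last titration point is not guaranteed.

The hyperbolic FP form assumes titrant in excess of probe. When the fitted
`Kd` falls at or below the probe concentration (the tightest chaperone
interactions here), the hyperbola overestimates `Kd`; a ligand-depletion
(quadratic) variant is available via `fit_fp_one_site(depletion = TRUE,
probe_conc = ...)` but is not the default, matching common practice for
these assays. The tests pin the direction of that bias.

## Identifiability under noise

The recovery tests perturb synthetic curves with Gaussian noise
proportional to the expected response (relative SD 5%), the natural error
model for densitometry-derived readouts where band-quantification error
scales with band intensity. The distinction matters for what recovery can
promise: with *additive* noise of 5% of the full amplitude on a 10-point
log-spaced design spanning `Kd/30`–`30·Kd`, the Fisher information of the
design caps any unbiased estimator at ≈ 20% relative SD on `Kd` (≈ 14%
median absolute error) — no fitting procedure can do better, and ours sits
at that bound. Under the proportional model the low-concentration points
are nearly noise-free, the design is far more informative, and the
measured median relative error is ≈ 8%. The tests therefore assert the
sub-10% median under proportional noise, which is the regime the assays
inhabit.

# Mass photometry

Contrast→mass calibration is a least-squares line through standards
(default 73, 149, 479, 800 kDa). Landing-event histograms are fit as
univariate Gaussian mixtures with a shared component SD
(expectation–maximisation, `k` chosen by the caller). Fitted peak masses
are assigned to `a ×` chaperone `+ b ×` clamp-trimer compositions by
exhaustive enumeration, minimising the absolute mass residual with ties
broken toward fewer total copies, then fewer chaperone copies. The default
assignment tolerance is deliberately generous (50 kDa): instrument-fitted
masses of multi-subunit assemblies can deviate substantially from naive
subunit sums (a measured ≈ 430 kDa peak versus a 470 kDa two-chaperone +
trimer sum), and a tight tolerance would spuriously unassign real peaks.
The default component masses (190 kDa chaperone, 90 kDa clamp trimer) are
configurable.

# Problem sizes and determinism

All generators are bit-reproducible under a fixed seed. The test suite
uses sizes chosen to make sampling error a small fraction of each
tolerance while keeping the full run in tens of seconds: 20,000 read pairs
for percent-nicked recovery (binomial SE ≈ 0.35 points), 2,000-bin tracks
at 50–80 expected reads per bin for partition recovery, 100 seeds per
affinity for noisy binding-fit medians, 3,000 events for mixture-peak
recovery. The acceptance script regenerates everything from scratch at the
same sizes.

# Known limitations

* The mapper is exact-match only; reads with sequencing errors go
  unmapped rather than being rescued. That is by design for synthetic
  validation, not a general-purpose aligner.
* Initiation zones are an *input* to the meta-profile machinery; the
  package does not call them from Okazaki-fragment data.
* Gel analysis starts from 1-D lane vectors; image processing, lane
  finding and 2-D gels are out of scope.
* No multi-curve/global binding fits and no cooperative two-site models.
* The synthetic generators validate arithmetic correctness; they are not
  simulators of real library noise (no error model, no duplicates, no
  chromatin structure).
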