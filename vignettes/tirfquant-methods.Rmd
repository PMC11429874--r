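---
title: "Models and methods in tirfquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tirfquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfquant)
```

`tirfquant` quantifies plasma-membrane recruitment of lipid biosensors
imaged at single-molecule level in TIRF microscopy. This vignette is the
package's own account of the models it implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## 1. The measurement problem

A biosensor expressed at single-molecule densities appears in TIRF as
diffraction-limited puncta. Three questions define the analysis chain:

1. *How many molecules are at the membrane?* — detect puncta per frame
   and count them per unit footprint area (molecules per 100 µm²).
2. *Are the puncta single molecules?* — deconvolve the spot-intensity
   histogram into monomer/dimer/trimer fractions against a monomeric
   calibration reporter.
3. *How fast does recruitment rise and fall after stimulation?* — fit
   the density (or normalized fluorescence) time course with a two-phase
   cooperative kinetic model.

A fourth, independent stage quantifies fixed-cell immunofluorescence
(per-cell AKT phosphorylation versus biosensor expression) from
four-channel stacks.

## 2. Synthetic scenes as ground truth

Every stage is validated against simulated inputs whose true answer is
known by construction.

**Single-fluorophore intensities** are lognormal. The generating
parameters are free parameters of the package (they are
instrument-specific and not dictated by any published value): defaults
`log_mean = log(500)` (ADU), `log_sd = 0.3`. The 0.3 log-width is the
regime in which the stoichiometry module's scaled basis is a good
approximation (section 4); wider distributions degrade it, and tests
probe exactly this default.

**Multimer spots** are generated *physically*: a c-mer intensity is the
sum of c independent monomer draws. The stoichiometry module instead
models a c-mer by the scaling transform (section 4). This mismatch is
deliberate — the generator provides an independent truth against which
the stated analysis model is tested. At `log_sd = 0.3` the recovered
fractions stay within ±0.05–0.07 of truth (test suite); at larger
log-widths the gap grows.

**Camera frames** render each spot as an *integrated* symmetric 2D
Gaussian (exact pixel integrals via the normal CDF, truncated at ±5σ),
add a constant background, apply Poisson shot noise, then Gaussian read
noise and a digital offset, and clip to the bit depth. Defaults follow
the acquisition geometry the package targets: pixel size 0.0867 µm (a
6.5-µm camera pixel, 2× binning, 150× total magnification), PSF
σ = 0.09 µm (an 0.21-µm Airy diameter ≈ 2.33 σ), 16-bit TIRF frames and
12-bit immunofluorescence channels.

**Time-lapse scenes** draw each frame's molecule count as Poisson with
mean `area × (baseline + Δpeak × F̂(t)) / 100`, where `F̂` is the
two-phase model rescaled to peak at 1, so the peak expected density is
exactly `baseline + Δpeak` (defaults 5 and 20 per 100 µm² — a ~5-fold
rise to ~25). Photobleaching multiplies the expectation by
`(1 − bleach_rate)^frame`; this is the marginal law of per-spot geometric
bleaching. Molecule identities are *not* tracked across frames — the
analysis counts, it does not track — so spot positions and intensities
are redrawn each frame.

**Immunofluorescence fields** place non-overlapping disk nuclei with
surrounding cytoplasm territories; per-cell EGFP means are lognormal
(bright law for the transfected fraction, dim law for the rest, chosen
so the dim population's mean + 3 SD sits below the 100-ADU positivity
cutoff), and the pS473 channel mean depends on the treatment flag, with
an optional inhibitory Hill coupling to EGFP (IC50 = 300 ADU, exponent 2)
to emulate suppression of AKT activation in high-expressing cells.

Not emulated (and therefore not demonstrated by passing tests): spectral
crosstalk, evanescent-field depth, pixel-dependent sCMOS noise maps,
realistic cell morphologies, lateral diffusion and blinking. Conclusions
about real data should bear these gaps in mind.

## 3. Spot detection

Each frame is band-pass filtered with a difference of Gaussians at
σ = 1 and 2 px (a standard stand-in for the B-spline wavelet filters of
SMLM packages; exact equivalence to any particular tool is not claimed).
Candidates are 8-connected strict local maxima of the filtered frame.
Two thresholds apply, both in units of the filtered frame's robust SD
(1.4826 × MAD, so bright spots do not inflate the scale):

* `threshold_k` (default 1.5) — the candidate threshold;
* `min_significance` (default 5) — the matched-filter significance an
  *accepted* spot must reach.

The second filter exists because smoothed noise produces many local
maxima above 1.5 robust SDs; requiring the band-pass response — which
for a true spot is a matched-filter statistic with high contrast — to
exceed 5 robust SDs suppresses them to below 0.05 false spots per
100 µm² per blank frame while leaving recall at peak-SNR ≥ 8 intact. A
covariance-based test on the fitted intensity was evaluated and
rejected: in a 7×7 px window the intensity/σ/offset trade-off inflates
the standard error so strongly that genuine SNR-8 spots fail it.

Candidates are refined by least squares with an integrated symmetric 2D
Gaussian plus constant offset (`fit_window` 7×7 px). Fits are discarded
if the center leaves the window, the intensity is non-positive, or σ
falls outside 0.5–3× the PSF expectation. Survivors closer than one
fitted Gaussian radius (the median fitted σ) are merged to the brighter —
refits of the same emitter collapse onto the same center, while genuinely
resolvable pairs sit farther apart. At 25 molecules per 100 µm² (the
density regime of interest) recall and precision both exceed 0.95 at
peak SNR 8; at 50 per 100 µm² about 7% of uniformly placed emitters fall
within one filtered-PSF width of a neighbour and merge into single
maxima — a diffraction limit no single-emitter detector escapes, so
recall declines toward ~0.92 there.

Conventions: pixel centers at (i − 0.5) × pixel size; ROIs in µm with
half-open pixel binning; each frame is counted independently. Densities
are `100 × count / area(µm²)`. Bulk traces subtract the *modal* pixel
intensity per frame (1-ADU histogram bins; the mode is sensor area
outside cells) and normalize to the pre-stimulus mean, which makes the
result exactly invariant to adding a constant to every pixel.

## 4. Intensity-histogram stoichiometry

The intensity density of a population with fractions $A_c$ of c-mers is
$\rho(x) = \sum_{c=1}^{M} A_c\,\rho_c(x)$ with $\sum A_c = 1$; absolute
counts are $A_c N$. The monomer basis $\rho_1$ is the normalized
histogram of a monomeric calibration reporter; higher orders use the
scaling transform with its change-of-variables Jacobian,
$\rho_c(x) = \rho_1(x/c)/c$. This reading of the transform is the
default; the physically exact alternative for independent emitters — the
c-fold self-convolution of $\rho_1$ — is available via
`build_basis(mode = "convolution")`. For a lognormal monomer law with
log-width 0.3 the two differ little; the default follows the scaling
formulation, and the test suite quantifies the residual bias against
summation-generated truth (±0.07 bound).

Defaults: M = 3 (monomer/dimer/trimer), Freedman–Diaconis bin width on
the calibration sample, one shared grid for basis, observation and
mixtures (the grid spans 1.05 × M × the calibration maximum so no c-mer
mass is clipped).

The reduced χ² uses Poisson variances, `max(exp, 1)` in the denominator,
and pools bins left-to-right until each pooled bin has ≥ 5 expected
counts (a trailing deficit merges into the last pooled bin);
`dof = B − n_params − 1`. Under its Poisson null the statistic's mean is
B/(B−1) ≈ 1, which the suite verifies over 500 replicates.

Fitting minimizes the reduced χ² over the simplex. Two objectives are
provided. The *deterministic* objective compares observed counts to
`N × ∫_bin ρ(x) dx`. The *stochastic* objective (default,
`n_resamples = 25`) draws N samples from the candidate mixture per
resample and compares histograms — the literal Monte-Carlo reading of
fitting "randomly generated intensity distributions"; common random
numbers (one uniform stream fixed by `seed`) make it smooth in A and
reproducible. Optimization is a coarse 0.01-step simplex grid evaluated
on the cheap deterministic objective, then hill-climbing refinement of
the selected objective down to step 0.0025; running the Monte-Carlo
objective at every one of the 5,151 grid nodes (M = 3) would cost
minutes for no benefit, since the two objectives agree within ±0.03 in
$A_1$ (tested). The *reported* `reduced_chisq` is always the
conventional observed-vs-expected statistic at the fitted proportions:
the Monte-Carlo criterion compares two noisy histograms and concentrates
near 2 even for a perfect model, so it is an optimizer's yardstick, not
a goodness-of-fit report.

Per-experiment fractions are pooled with a t-interval on the mean
(`pool_fraction`); near-saturated fractions can yield intervals
exceeding 100%, which is reported as-is.

## 5. Two-phase translocation kinetics

For t ≥ 0,
$$F(t) = F_{max}\left[\frac{t^{n_{syn}}}{t^{n_{syn}}+\tau_{syn}^{n_{syn}}}
 - \frac{t^{n_{deg}}}{t^{n_{deg}}+\tau_{deg}^{n_{deg}}}\right],$$
and $F(t) = F_0$ for t < 0; $k_{syn} = 1/\tau_{syn}$,
$k_{deg} = 1/\tau_{deg}$ (exact reciprocals in every report). The form is
descriptive — a cooperative rise and fall — not a mechanistic pathway
model; note its tail decays algebraically (t^−n), so "first-order"
decay-rate summaries (`fit_first_order_decay`) are meaningful on the
early post-peak window only. Hill terms are evaluated as
`1/(1 + exp(n (log τ − log t)))`, which never overflows.

Choices made where the design was open:

* **F0 is fixed at 0 by default.** For normalized data
  (F = ΔF/ΔF_max) the t ≥ 0 branch already vanishes at t = 0, so a free
  F0 would only introduce a discontinuity; a flag frees it for raw
  traces.
* **Separate Hill coefficients per phase**, both free by default in
  [0.5, 10]; τ in [0.05, 100] min; Fmax in [0.1, 10]. The two exponents
  are structurally near-degenerate with the rates: the model admits a
  near-cancellation ridge (large Fmax with τ_syn ≈ τ_deg) that can be
  the genuine least-squares optimum for noisy traces, and with all five
  parameters free the information bound on the rates is of order 15% at
  realistic noise. `fix_n` therefore constrains the exponents when they
  are known or assumed — the package's recovery studies fix n = 2, the
  generating value — and this is the recommended mode whenever rates,
  not exponents, are the quantity of interest.
* **Multi-start fitting**: five deterministic initializations seeded
  from the observed peak time (plus an optional user guess), best SSR
  kept, bounded Levenberg–Marquardt underneath.
* **Profile-likelihood CIs at Δχ² = 3.84** on the concentrated
  (unknown-variance) log-likelihood, `n·log(SSR/SSR_min) = 3.84`. At
  every profile point the nuisance parameters are re-optimized from the
  previous point's warm start *and* from all deterministic starts,
  taking the minimum — a single warm start can get trapped on the ridge,
  which overestimates the profile and collapses the intervals. With the
  multi-start profile the 95% intervals calibrate inside 90–98% coverage
  in the package's 100-replicate study. Rate-constant intervals are the
  reciprocals of the τ intervals. Fits whose τ_deg estimate or interval
  reaches the bound box are flagged `tau_deg_unidentifiable`, never
  silently reported.
* **Weighting**: 1/se² when the trace carries standard errors, else
  unweighted. Time origin: stimulus at t = 0, pre-stimulus samples
  negative.

Normalization modes: `delta_over_deltamax` (pre-stimulus mean 0, max 1),
`fold_over_baseline` (doubling = 100% increase), `max_normalized`.

## 6. Immunofluorescence quantification

The Huang fuzzy-entropy threshold is computed on a 256-bin histogram
scaled to the image min–max — the ImageJ dialect for deeper-than-8-bit
data — by exhaustive scan of candidate bins; membership is
`1/(1 + |g − μ_class|/C)` with C the occupied grey-level range, and the
threshold minimizes the summed Shannon fuzziness. The test suite checks
it bin-for-bin against an independently written brute-force scan.

Segmentation: nuclei = Huang-thresholded DAPI, single-pixel holes
filled, split by watershed on the distance transform with an h-maxima
tolerance of 2 px (enough to ignore boundary-noise bumps on ~8-px-radius
nuclei without missing genuine pairs); cell territories = Huang-
thresholded CellMask (holes filled, united with the nuclei) partitioned
by geometric propagation of the nucleus labels — the Voronoi recipe — so
each cell contains exactly one nucleus and segmentation is fully
deterministic.

Filters and measurements follow strict printed conventions: area
> 10 µm² (a cell of exactly 10 µm² is removed), no border contact,
EGFP > 100 ADU for transfection (strict; checked against mean + 3 SD of
an untransfected reference when supplied, with a warning if the cutoff
is not above that bound), raw EGFP means (background subtraction applies
to pS473 only, using the mean of no-primary-antibody control cells,
clamped at zero). Group summaries report medians with exact
order-statistic (binomial) 95% CIs — appropriate for the skewed staining
distributions — and the comparison report is standard plumbing:
Kruskal–Wallis with Holm-adjusted pairwise Wilcoxon tests, or one-way
ANOVA with Tukey HSD for normal data.

## 7. Copy-number arithmetic

`converted_pool`, `molecules_per_cell`, `allele_scaled_copies`,
`percent_of_pool`, `airy_disc_area`, `convolution_density_limit`,
`sphere_volume_pL` and `concentration_nM` encode the bookkeeping that
connects measured membrane densities to whole-cell copy numbers,
diffraction-limit densities and concentrations. One unit note: a 15-µm
*diameter* sphere is 1.77 pL, and 5 × 10⁵ molecules in that volume is
~470 nM; the package computes volumes from diameters honestly rather
than adopting any rounded figure.

## 8. Problem sizes and reproducibility

The validation suites run at sizes chosen to give stable statistics on a
single CPU: stoichiometry recovery at N = 10⁴ spots against a 2 × 10⁴
calibration; kinetics bias/coverage over 100 replicate traces (27–33
samples each at 30-s spacing); detection recall/precision over 100
simulated 13 × 13 µm frames at 25 molecules per 100 µm²; the χ² null
over 500 replicates of 100 bins; segmentation over scenes of 12 cells.
All generators take explicit seeds and are bit-reproducible given a
seed; `scripts/acceptance.R --seed S --out f.json` re-runs the whole
chain from scratch.

## 9. Known limitations

* Single-emitter detection: unresolvable sub-diffraction pairs merge
  (section 3); no multi-emitter fitting, tracking, drift correction or
  bleaching-step counting.
* The scaled c-mer basis is an approximation to the sum-of-emitters
  law; use the convolution mode for wide monomer distributions.
* The two-phase model is descriptive; parameters map onto pathway
  biochemistry only loosely, and its algebraic tail limits first-order
  summaries to the early decay.
* The kinetic profile CIs assume independent Gaussian residuals;
  autocorrelated noise (e.g. slow focus drift) would miscalibrate them.
* Segmentation expects well-separated, roughly convex cells (the
  watershed/Voronoi dialect of the ImageJ recipe); it is not a
  general-purpose cell segmenter.
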