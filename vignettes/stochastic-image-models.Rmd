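---
title: "Stochastic image models and pertinent-statistic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic image models and pertinent-statistic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Generative image models -- GANs and their successors -- are increasingly
proposed for medical-imaging tasks, yet the usual evaluation measures
(perceptual scores, ensemble feature distances) are blind to exactly the
per-image statistics a downstream diagnostic task may depend on.  A
productive way to probe this gap is to train or score a generative model
against a *stochastic image model* (SIM): a mathematical procedure that
generates random images with known, controllable statistical structure.
Because every property of the reference distribution is known, any
discrepancy in a pertinent statistic is attributable to the candidate
model rather than to uncharacterized data variability.

`simeval` implements three canonical SIM families, the per-image
statistics pertinent to each, and a comparison harness that scores any
candidate ensemble against a reference SIM with Jensen--Shannon (JS)
divergences, each accompanied by a matched *noise floor* -- the value the
same metric takes between two independent draws of the reference itself.

# The clustered lumpy background (CLB)

The CLB model produces mammography-like texture as a two-level Poisson
process.  A Poisson number of cluster centres (expectation
`mean_cluster_count` per image area) is placed uniformly over a field
extended beyond the image border; each cluster receives a Poisson number
of blobs (expectation `mean_blobs_per_cluster`) displaced from the
cluster centre by isotropic Gaussian offsets of standard deviation
`cluster_spread` pixels.  Every blob contributes the profile

$$b(u, v) = \exp\!\left[-\alpha\,\Big(\big(u/L_x\big)^2 +
\big(v/L_y\big)^2\Big)^{\beta/2}\right]$$

in its own, possibly rotated, coordinates, and contributions are summed.
A monotone gray mapping (offset, scale, clip range) converts the raw sum
to display values.

Five named configurations ship as editable flat-text config files:
`opex99` (the original single-layer parameterization: $\bar K = 150$,
$\bar N = 20$, $L_x = 5$, $L_y = 2$, $\alpha = 2.1$, $\beta = 0.5$,
cluster spread 12 px) and four variants -- single or double layer,
isotropic or oriented clusters (`simpiso`, `simpori`, `doubiso`,
`doubori`).  The historical parameter tables for the variants are
external to this package, so their numeric defaults are documented
placeholders chosen to produce a coarse structural layer
plus a fine textural layer; every package invariant (determinism,
stationarity, additivity, clip-range containment) holds for any valid
setting, and the config files are data, not code.

Numerical choices:

* **Border extension.**  Cluster centres are sampled over a margin of
  (blob kernel reach) + 3 x `cluster_spread` beyond each image edge.
  The kernel reach alone would bound the truncation of blob mass, but
  blobs land up to several spread standard deviations from their
  cluster centre; ignoring that term would leave a visible edge deficit.
  The left/right and top/bottom half-mean agreement of a generated
  ensemble is tested to below 1%.
* **Orientation grid.**  Blob profiles are accumulated from kernels
  precomputed on a discrete grid of 16 angles over $[0, \pi)$; drawn
  orientations (uniform per blob in the isotropic modes; one preferred
  direction per cluster plus Gaussian jitter in the oriented modes) are
  snapped to the grid.  A $\pi/16$ angular quantization is far below the
  angular scale of the blob profiles and makes desk-scale ensembles
  (thousands of images) practical.
* **Kernel truncation.**  Profiles are cut where they fall below 1% of
  their peak.  With $\beta = 0.5$ the profile tail is heavy, so the cut
  discards a spatially near-uniform haze; the stationarity and
  additivity tests quantify that no structured artifact is introduced.
* **Double layers** combine by pixelwise sum *before* gray mapping, the
  simplest composition consistent with a layered model; the sum is exact
  and tested.

```{r}
library(simeval)
cfg <- clb_config("doubiso")
e <- generate_clb_ensemble(cfg, n = 4, seed = 1)
plot(e, 1)
```

# B-mode ultrasound speckle (USS)

Speckle is modelled as a random phasor sum: scatterers form a Poisson
point process, each carrying unit amplitude and an independent phase
uniform on $[0, 2\pi)$; the scatterer map is convolved with a complex
point spread function (PSF) whose Gaussian envelope is set by the axial
and lateral resolutions and which is modulated axially by the two-way
carrier.  With $\lambda = v / f_c$, the resolution cell is

$$AR = N_c \lambda / 2, \qquad LR_y = \lambda f_{\#y}, \qquad
LR_z = \lambda f_{\#z}, \qquad V_{cell} = AR \cdot LR_y \cdot LR_z,$$

and the expected number of scatterers per resolution cell is
$N = \mathrm{SND} \times V_{cell}$, where SND is the scatterer number
density in mm$^{-3}$.  The defaults ($v = 1556$ m/s, $f_c = 3.5$ MHz,
$N_c = 2$, f-numbers 2 and 3, 100 um pixels, 256 x 256) give
$\lambda = 0.4446$ mm and $V_{cell} = 0.527$ mm$^3$.

For small $N$ the speckle is non-Gaussian and carries information about
the scatterer density; as $N$ grows the envelope becomes Rayleigh and
the intensity exponential (fully developed speckle).  The per-image
pertinent statistic is the intensity signal-to-noise ratio
$SNR = \mu_I / \sigma_I$ and the derived estimate
$\hat N = SNR^2 / (1 - SNR^2)$, defined for $SNR^2 < 1$.

**The AR/LR-to-sigma convention.**  How the stated resolutions map to
the PSF's Gaussian standard deviations is a convention, and the package
isolates it in one function (`speckle_psf_geometry()`).  The default,
*cell-matched*, sets $\sigma_x = AR/\sqrt{2\pi}$,
$\sigma_y = LR_y/\sqrt{2\pi}$ and collapses the elevational dimension
into the areal scatterer density $\rho = \mathrm{SND} \times LR_z$.
For any filtered-Poisson phasor model the effective scatterer number
governing the speckle statistics is
$N_{eff} = \rho\,(\int |h|^2)^2 / \int |h|^4 = 2\pi \sigma_x \sigma_y
\rho$, so this choice makes $N_{eff} = \mathrm{SND} \times V_{cell}$
*exactly*: $\hat N$ is then a calibrated estimator of the physical
scatterers-per-cell count.  The package validates this empirically --
the acceptance suite simulates 2000 images at SND-1, applies the 8-bit
conversion, and checks that the ensemble mean $\hat N$ matches the
reference value for that configuration within 10%.  An alternative
`"fwhm"` convention (AR and $LR_y$ read as the envelope full width at
half maximum) is provided for sensitivity analysis.

**8-bit conversion.**  Ensembles are converted to unsigned 8-bit
grayscale in which 255 corresponds to the pooled 99th-percentile pixel
value (linear-interpolation percentile); roughly 1% of pixels saturate,
and the realized fraction is logged.  The order of operations is fixed
and matters: the pertinent per-image statistics are computed on the
quantized ensemble (intensity = squared 8-bit envelope), matching the
canonical preprocessing of GAN training data.  Quantization and
saturation *raise* per-image $SNR^2$ by a mild, density-dependent
factor (about 1.1--1.2 in our measurements); at high SND this can push
$SNR^2$ above 1, in which case $\hat N$ is flagged undefined for that
image rather than extrapolated.

**A structural limit worth knowing.**  Within this model class the
pre-quantization $SNR^2$ equals $N_{eff}/(1 + N_{eff})$ with $N_{eff}$
strictly proportional to SND -- any filtered Poisson process with i.i.d.
marks has this property.  Reference values whose implied
$\hat N/\mathrm{SND}$ ratio varies strongly with SND therefore cannot
all be matched by any single convention; this package anchors its
calibration at the low-density end (SND-1), where the scatterer-count
estimation problem is well posed, and reports the other densities as
computed.

```{r}
p <- uss_physics(snd = 1)
resolution_cell(p)
e <- generate_uss_ensemble(p, n = 100, seed = 1)
q <- quantize_ensemble_8bit(e)
st <- speckle_stats_table(q)
fit_gaussian_pdf(st$snr2)
```

# The stylized breast-slice model (S2V)

The third family consists of 2-D labelled breast slices: each pixel is
one of ten tissue classes (fat, glandular, skin, artery, vein, muscle,
ligament, nipple, terminal duct lobular unit, background), converted to
an X-ray attenuation image by assigning each class its linear
attenuation coefficient at 30 keV.  The per-image pertinent statistic is
the fat-to-glandular ratio $\rho_{F:G} = F/G$, where $F$ and $G$ count
pixels within 1.5% (relative) of the fat and glandular coefficients
respectively -- the two coefficients are far enough apart that the
threshold cannot confuse them, which the `attenuation_table()`
constructor enforces.  The packaged coefficient table holds editable
defaults in the range reported for breast tissues in the standard
attenuation literature; only the fat/glandular separability matters to
the statistics.

Because the anthropomorphic 3-D phantom tools that would normally supply
labelled volumes are external, the package ships its own **surrogate
label-map generator** (`sample_surrogate_phantom_slice()`), clearly a
synthetic stand-in: a perturbed-ellipse interior with a skin rim,
optional thin vessels, and a fat/glandular partition obtained by
thresholding a smooth Gaussian random field at the empirical quantile
that realizes a target ratio.  Targets are drawn from a four-component
log-ratio mixture mimicking the four clinical breast-density types
(default prevalences 10/40/40/10%, mode centres 2.2, 1.1, 0.1, -1.0 in
natural-log ratio, s.d. 0.25).  The construction realizes the drawn
target within a configured tolerance (default 5%) by exact rank
thresholding, and errors on infeasible targets.  The surrogate preserves
the *statistic under test* -- a controllable multi-mode
$\log \rho_{F:G}$ distribution -- and makes no claim to anatomical
realism; conclusions about real phantom anatomy do not follow from tests
that pass on the surrogate.

Slice handling utilities cover the labelled-volume path: coronal slices
are taken between 40% and 70% of the volume depth at a 50-plane spacing
(`seq(ceiling(0.4 d), floor(0.7 d), by = 50)`), and downsampling is
label-preserving (nearest neighbour).  Downsampling labels *before*
coefficient assignment avoids partial-volume pixels that belong to no
tissue class; this ordering is a deliberate choice and is stated here
because the alternative (downsampling the attenuation image) would
create intermediate values that the thresholding statistic would
silently drop.

# Ensemble statistics and the comparison harness

* **Gray-level PDFs** are pooled-pixel histograms, density normalized.
* **Radial autocorrelation**: each image is mean-subtracted, tapered by
  a radial Papoulis window ($w(r) = |\sin \pi r|/\pi +
  (1 - r)\cos \pi r$), transformed, and the ensemble-averaged spectral
  autocorrelation is normalized to 1 at zero lag and radially averaged
  over integer-lag annuli.  The taper suppresses the boundary artifacts
  of the circular convolution.
* **JS divergence** is estimated on shared equal-width bins spanning the
  pooled sample range (default 64 bins), in natural-log units, bounded
  by $\log 2$.  The bin count is a documented knob; the finite-sample
  floor of the estimator is why every comparison is paired with a
  matched noise floor computed the same way.
* **Gaussian fits** to empirical $SNR^2$ PDFs are least-squares fits of
  a Gaussian *density* to the binned histogram (Nelder--Mead on
  $(\mu, \log\sigma)$, initialized at the sample moments), reporting
  $\mu$, $\sigma$ and the mean squared error of the fit.
* **Two-component feature PDFs**: the 17 texture features of both
  ensembles are standardized symmetrically -- centred on the midpoint of
  the two table means and scaled by the root-mean *within-table*
  variance -- before pooled PCA and projection onto the first two
  components.  Standardizing by the mixed-sample standard deviation
  instead would absorb any between-ensemble displacement of a feature
  into its scale and hide it from the leading components; the symmetric
  form keeps the comparison order-invariant and affine-rescale
  invariant while leaving mode displacement visible.

The 17 texture features are: mean, standard deviation, skewness and
kurtosis of the pixel distribution (population-moment convention;
flagged `NA` on constant images); energy, entropy (natural log),
maximum, contrast and homogeneity of the gray-level co-occurrence
matrix (distance 1 at 0/45/90/135 degrees, symmetrized, normalized per
offset and averaged -- making the feature set invariant to 90-degree
rotations); short/long primitive emphasis and gray-level/primitive-
length uniformity of the run-length matrix (runs pooled over the four
directions); and coarseness, contrast, complexity and strength of the
neighbourhood gray tone difference matrix (radius-1 window, interior
pixels only, coarseness stabilized by `epsilon = 1e-6` so a constant
image yields `1/epsilon`).  Quantization to 32 gray levels, the
distances, angles and window radius are all `texture_config()` knobs;
every matrix builder is verified against brute-force enumeration
oracles on randomized small images in the test suite.

`compare_ensembles()` runs the suite appropriate to the model family --
texture-feature JS (per feature, aggregated by mean by default, and the
2-D PCA PDF JS) for CLB; $SNR^2$ JS for USS; $\log\rho_{F:G}$ JS for
S2V; gray-level-PDF JS and the maximum absolute autocorrelation-profile
difference for all -- identically on both ensembles, and serializes the
report to JSON.  `noise_floor()` applies the same suite to two
independent reference draws.  The autocorrelation *scalar* (maximum
absolute profile difference) is this package's own summary; the
underlying profiles are what the field usually inspects.

# Study conditions and problem sizes

The evaluation conditions the package reproduces are: 256 x 256 images;
the USS physics above with SND in {1, 2, 3, 30} mm$^{-3}$; 8-bit
top-1% conversion before per-image statistics; multi-class ensembles
mixed 50/50 or 95/5, the degraded CLB class produced by a Gaussian blur
(default $\sigma$ = 2 px, a documented knob) followed by an ideal
low-pass at half the image bandwidth
(radial cutoff 0.25 cycles/pixel).  The default evaluation ensemble
size is 10,000 images; the package's own test suite and acceptance
script use 2,000 images per ensemble (and 128-pixel CLB/USS canvases
with area-scaled cluster counts for the harness detection checks),
sizes at which the distributions of the statistics are stable and the
full suite runs at desk scale.  Detection checks assert that a
constructed defect -- a half-degraded class, a dropped 5% minority
class, a wrong scatterer density, a mismatched breast-type mixture --
lifts at least one pertinent-statistic JS well above its matched noise
floor, while two independent reference draws sit at the floor.

# Limitations

* The CLB variant parameters are placeholders, not the historical
  tables; comparisons across this package's configurations are
  internally consistent but not numerically tied to the original
  optimized parameterizations.
* The USS convention is anchored at SND-1; see the structural-limit
  note above for why the whole SND range cannot be matched at once by
  one linear-physics convention.
* The surrogate breast slices share only the ratio statistic's
  structure with real anthropomorphic phantoms, not anatomy.
* JS estimates depend on binning; always read them against their
  matched noise floor, which the harness computes with the identical
  binning.
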