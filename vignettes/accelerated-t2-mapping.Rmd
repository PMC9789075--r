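---
title: "Accelerated T2 mapping: models, losses and evaluation in AccelT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated T2 mapping: models, losses and evaluation in AccelT2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(AccelT2)
```

## The problem

Quantitative T2 relaxometry maps the transverse relaxation time of tissue
voxel by voxel from magnitude images acquired at several echo times (TEs).
In musculoskeletal imaging the tissues that carry the diagnostic signal —
articular cartilage in the knee and hip, intervertebral discs (IVDs) in the
lumbar spine — are thin structures occupying a small fraction of the field
of view, and T2 changes of order 5–15 % within them are clinically
meaningful. Multi-echo mapping acquisitions are slow; sampling fewer
phase-encode lines in k-space accelerates them at the cost of aliasing
artefacts that the reconstruction must remove without corrupting the T2
values or the fine texture inside the tissue of interest.

AccelT2 implements the complete simulation-and-evaluation chain for this
problem: synthetic multi-echo phantoms with known ground truth,
retrospective k-space undersampling with the acquisition geometry of a
3D Cartesian mapping sequence, mono-exponential T2 fitting, a recurrent
UNet that predicts T2 maps directly from aliased echo images, an
ROI-weighted multi-component training objective, and an evaluation battery
centred on ROI-restricted error, agreement and texture retention.

## Signal model and phantoms

Each voxel follows the mono-exponential decay

$$ S(\mathrm{TE}) = A \, e^{-\mathrm{TE}/T_2}, $$

with the amplitude $A$ proportional to proton density. The knee and spine
presets use TEs of 0, 12.9, 25.7 and 51.4 ms; the hip preset uses 0, 10.4,
20.8 and 41.7 ms. Magnitude images carry Rician noise: two independent
Gaussian channels of standard deviation `noise_sigma * max(PD)` combined in
quadrature, so background magnitudes have mean $\sigma\sqrt{\pi/2}$.

`generatePhantom()` builds aligned multi-echo stacks in which a thin,
curved, two-compartment "cartilage" arc (2–6 pixels thick) or a set of
elliptical "IVD" regions is embedded in a lower-T2 tissue background.
Default tissue values — background 20 ms, cartilage 30–60 ms with +15 ms
focal lesions for the knee; 25–55 ms for the hip; discs 60–130 ms on a
40 ms background for the spine — place the tissues of interest inside the
sensitive band of the corresponding sigmoid loss operator (below). The
default 2 % noise level corresponds to a TE = 0 tissue SNR of roughly 35–50,
a realistic regime for coil-combined magnitude data. The generator is
fully seeded and bit-reproducible.

What the phantoms deliberately do **not** emulate: anatomically realistic
geometry, $B_0$/$B_1$ inhomogeneity, motion between echoes (all inputs are
aligned by construction, so the registration step a real pipeline needs is
out of scope), multi-coil acquisition physics, and multi-component decay.
Tests that pass on these phantoms validate the algorithmic chain, not
clinical performance.

## Retrospective undersampling

Undersampling acts on the two phase-encode axes $(k_y, k_z)$; the readout
is always fully sampled. Three geometric ingredients match the target
acquisition:

* **Elliptical coverage.** Only points inside a centred, axis-aligned
  ellipse occupying 0.7 of the rectangular $k_y$–$k_z$ area are ever
  acquired; corner k-space is skipped. `ellipticalSupport()` adjusts the
  discrete semi-axes so the realised pixel-count fraction is within
  ±0.01 of the request.
* **Fully sampled centre.** A central region occupying 5 % of the grid
  area (sides proportional to the grid extents, rounded to odd lengths for
  symmetry about DC) is sampled in every echo's mask.
* **Center-weighted Poisson disc.** Remaining points are drawn by
  dart-throwing with an exclusion radius growing linearly with the
  normalised elliptical radius, $r(d) = r_0 (1 + \alpha d)$ with
  $\alpha = 2$ by default. $r_0$ is calibrated by bisection so that
  (ellipse points) / (sampled points) matches the target acceleration
  factor R within 2 %; because dart-throwing counts move in integer
  jumps, a final blue-noise-preserving correction adds the candidate
  farthest from all accepted points (or removes the most crowded
  non-central point) until the budget is met. R is defined relative to
  elliptical coverage, and the central region counts toward the sampled
  points.

Each echo gets a unique pattern from a deterministic per-echo seed offset.
Unsampled lines at one echo are initialised from the temporally closest
echo that sampled them (ties resolved toward the earlier, higher-signal
echo); lines sampled at no echo are zero-filled. Volumes are Fourier
transformed along the phase-encode plane (DC centred, fftshift
convention, 0-based grid indices), masked and shared, and inverse
transformed; magnitudes of the result are the aliased images.

## T2 fitting

`fitT2()` estimates $(A, T_2)$ per voxel by damped Gauss–Newton
(Levenberg–Marquardt) least squares on the magnitudes, initialised from the
log-linear regression of $\log S$ on TE over above-floor echoes. All
voxels are fitted simultaneously with vectorised 2×2 normal-equation
solves, per-voxel damping, and per-voxel step acceptance. Defaults:
bounds 1–300 ms (degenerate or non-decaying voxels clamp to a bound and
are flagged rather than diverging, keeping maps usable by the losses and
the texture quantisation), signal floor near zero, 30 iterations.
Magnitude (Rician) bias is deliberately not modelled — the fit matches
the standard ground-truth-map generation practice — and this is a known
limitation at low SNR.

## The training objective

The network loss is a weighted sum of four components,

$$ L = \lambda_{L_1} L_{L_1} + \lambda_{L_1,\phi} L_{L_1,\phi}
     + \lambda_{\mathrm{SSIM}} L_{\mathrm{SSIM}}
     + \lambda_{\mathrm{Feat}} L_{\mathrm{Feat}}, $$

where $\phi$ denotes the tissue-of-interest pixels. The two L1 components
compare sigmoid-rescaled maps: with

$$ S(x) = y_l + (y_h - y_l)\left(1 + e^{-\frac{10}{x_h - x_l}
   \left(x - \frac{x_l + x_h}{2}\right)}\right)^{-1}, $$

high T2 values — the ones most easily lost under acceleration — are
weighted up. Presets: knee $x_l = 0$, $x_h = 100$ ms, $y_l = 0.1$,
$y_h = 1$; hip $x_h = 60$ ms, $y_l = 0.5$; spine $x_h = 150$ ms,
$y_l = 0.25$. The absolute differences are reduced by the **mean** over
the relevant pixel set (global or $\phi$); a mean rather than a sum keeps
the weight ranges comparable across image sizes.

$L_{\mathrm{SSIM}} = 1 - \mathrm{SSIM}$ uses a 7×7 Gaussian window
(σ = 1.5), stabilisation constants $C_1 = 0.01^2$, $C_2 = 0.03^2$, over the
valid interior, with maps clipped to $[0, 1.5\,x_h]$ and rescaled to
[0, 1]; SSIM needs a declared dynamic range and this one covers the full
plausible T2 range of each anatomy.

$L_{\mathrm{Feat}}$ compares deep convolutional features of the two maps
after resizing to 224×224, channel-tripling and normalisation with the
standard channel means 0.485/0.456/0.406 and standard deviations
0.229/0.224/0.225. The extractor is dependency-injected;
`randomFeatureExtractor()` supplies a fixed-seed random convolutional
stack with the same interface, so the loss is self-contained,
bit-reproducible, and needs no external weight files. A pretrained deep
extractor can be plugged in through the same interface.

Weight search ranges per anatomy (used by `hyperparameterSearch()`,
uniform sampling): knee $\lambda_{L_1} = 1$, $\lambda_{L_1,\phi} \in
[50, 150]$, $\lambda_{\mathrm{SSIM}} \in [0, 2]$, $\lambda_{\mathrm{Feat}}
\in [0, 0.5]$; hip $\lambda_{L_1,\phi} \in [0, 3]$, $\lambda_{\mathrm{Feat}}
\in [0, 1]$; spine $\lambda_{L_1,\phi} \in [1, 10]$,
$\lambda_{\mathrm{SSIM}} \in [10, 100]$, $\lambda_{\mathrm{Feat}} \in
[5, 55]$. The search scores candidates on validation ROI NRMSE and ROI
Pearson correlation; since two criteria need a combiner, the winner
minimises the rank sum of NRMSE (ascending) and Pearson r (descending).

Every component has an analytic gradient with respect to the predicted
map (including SSIM, back-propagated through its windowed statistics, and
the feature stack), verified against central finite differences in the
test suite.

## Network architecture

Three variants map the 4 aliased echo images of a slice to one T2 map.

**Full model** (39,808,710 trainable parameters). A recurrent portion
followed by a UNet. Each echo passes through a 5-layer processing stream
of 3×3 stride-1 convolutions with depths 64, 128, 256, 512 and 1; the
stream weights are shared across echoes — this weight sharing over the
echo dimension is what makes the portion recurrent. 3×3 stride-1
convolutions with residual connections transfer information between
temporally adjacent corresponding hidden layers, scaled by
$\lambda_w = 0.2$; these hidden-to-hidden convolutions are likewise
shared across echo transitions. Each echo position applies a learned
per-channel gain to its hidden states (4 echoes × 960 channels),
letting the shared stream modulate per echo. Residual connections link
each input image to its stream output. The connection direction runs
from earlier to later echoes by default (earlier echoes carry more
signal) and is configurable.

The four stream outputs are concatenated and fed to a UNet: a 3×3
stride-2 convolution encoder with depths 64, 128, 256, 512, 1024; a
decoder of five levels, each a 4×4 stride-2 transpose convolution
(outputs 1024, 384, 48, 32, 68) followed by skip concatenation and a 3×3
refinement convolution (outputs 512, 192, 128, 116, 142). The first four
skips come from the encoder; the final, full-resolution level
concatenates the UNet input itself, so the decoder retains direct access
to full-resolution features. A 3×3 head convolution emits the map.

**No RNN** (35,116,037 parameters): the UNet alone, fed the concatenated
aliased images. **Reduced parameters** (9,958,246): the full architecture
with every depth halved except the inputs to the recurrent portion and
the UNet.

The published parameter counts are treated as the specification of
record: where the layer-level description leaves freedom (exact decoder
depths, the form of the per-echo modulation), depths were chosen so all
three counts are reproduced simultaneously and exactly; `nParameters()`
verifies this without allocating weights. Activations are leaky
rectifiers (slope 0.01) and there are no normalisation layers; the
parameter counts are unaffected by either choice. A fixed input prescale
(1/5000, no trainable parameters) maps the 0–500 working signal range to
order one inside the network so that activations — and with them the
output's sensitivity to one coherent optimiser step — are well
conditioned for the saturating sigmoid losses.

## Training harness

`trainModel()` follows the stated optimisation protocol: Adam at learning
rate 0.001 with batch size 1, per-step random rigid augmentation (the
identical translation/rotation applied to all echo images, the target map
and the ROI mask; bilinear resampling for images, nearest-neighbour for
masks, zero fill outside the frame), early stopping when the validation
loss has not improved for 10 epochs (configurable), and restoration of
the best-validation checkpoint rather than the last. Signals are scaled
per slice so the middle 95 % of pixel values spans 0 to 500 (knee,
spine) or 0 to 100 (hip); the percentiles are computed jointly over the
slice's four echo images so relative decay is preserved.

Three numerical safeguards, all configurable, condition the batch-1
optimisation of the saturating sigmoid losses. The first 25 optimiser
steps ramp the learning rate linearly from zero — the very first
coherent full-rate steps can otherwise throw the predictions out of the
sigmoid's sensitive band, where gradients vanish and momentum coasts.
The global gradient norm is clipped (default 5): single augmented
samples occasionally produce spiking, highly coherent gradients that
would derail an epoch. And the default learning-rate schedule anneals
cosine-shaped from the configured rate to 5 % of it across the epoch
budget, letting weakly-weighted loss components settle instead of
oscillating. Targets default to the maps fitted from the fully sampled
series — the reference a real pipeline trains against — with the exact
simulation truth available by flag. Everything is seeded; identical
seeds give identical loss curves.

The default augmentation bounds are ±10 pixels and ±5 degrees, matching
the protocol at acquisition-matrix scale; the desk-scale studies in the
tests use ±3 pixels on their 32-pixel phantoms, the proportional
equivalent.

## Evaluation battery

* `roiNrmse()`: $\| T_2 - \hat T_2 \|_{2,\phi} \, \| T_2 \|_{2,\phi}^{-1}$,
  the ROI-restricted normalised root-mean-square error;
  `t2Equivalent()` converts it to milliseconds by multiplying with the
  mean ROI T2.
* `pearsonRoi()`: voxel-wise Pearson correlation over the pooled ROI
  pixels of a scan, with a two-sided p-value.
* `blandAltman()`: bias and ±1.96 s.d. limits of agreement between paired
  compartment-mean T2 values (differences are prediction minus truth).
* `glcmMetrics()`: masked gray-level co-occurrence metrics — contrast and
  dissimilarity respond to sharp textures; homogeneity, angular second
  moment and energy to smooth ones. Maps are clipped to $[0, 1.5 x_h]$
  and uniformly quantised to 32 gray levels; symmetric co-occurrence
  counts are accumulated at distance 1 for orientations 0°, 45°, 90°,
  135° over pixel pairs **both** inside the ROI (excluding out-of-mask
  neighbours avoids mask-edge artefacts that zero-filling would create),
  pooled across the slices of a scan before normalisation, and each
  metric is averaged over the four orientations. The gray-level count and
  clipping range are not dictated by the evaluation framework itself;
  the defaults here are declared package choices.
* `iccSingleRater()`: intraclass correlation between a metric computed on
  truth maps and on predicted maps across scans, two-way model, single
  rater. The default is the consistency form ICC(3,1) =
  $(MS_R - MS_E) / (MS_R + (k-1) MS_E)$ with $k = 2$; an
  absolute-agreement form is available by flag, since a "two-way mixed
  effects, single rater" design admits both readings. Confidence
  intervals and p-values follow the standard F-distribution formulation.

## Desk-scale study sizes

The end-to-end properties are exercised at desk scale: phantoms of
32 × 32 × 8 voxels (phase-encode grid 32 × 8), the mask-geometry checks
on the full 128 × 22 acquisition-matrix grid, and the zero-fill
degradation trend over ten phantom seeds at R = 2, 4, 8.
`smokeBenchmark()` packages the training study: 16 training phantoms
(two central ROI slices each), each aliased under a small library of
three Poisson-disc mask realisations at R = 4 — exposing the network to
several undersampling patterns discourages memorising pattern-specific
artefacts — with a Reduced-Parameters network trained for up to 10
epochs and evaluated on 4 held-out phantoms against the zero-fill
fitting baseline. These sizes are the package's chosen study conditions
for its own reproducible benchmark; they are three orders of magnitude
below a clinical training run, which is why the benchmark compares
against the package's own zero-fill baseline rather than against
published patient-data error rates.

## Known limitations

* Plain magnitude least squares ignores the Rician noise floor; at low
  SNR the fitted T2 is biased.
* The synthetic phantoms are piecewise-constant with focal lesions; real
  cartilage has laminar T2 gradients and the texture statistics of real
  maps are richer than what the lesion model produces.
* The feature loss's default extractor is a random projection: it
  preserves textural differences in expectation but does not encode the
  semantic feature hierarchy of a pretrained network.
* Registration between echoes is out of scope; inputs are assumed
  aligned (an identity hook marks where a registration step would go in
  a real pipeline).
* The hip preset's undersampling geometry inherits the limitation that
  phase-oversampled acquisitions cannot be exactly emulated from
  cropped reconstructed images.
* At the benchmark's scale the trained network typically outperforms
  the zero-fill baseline on most held-out phantoms and on the high-T2
  compartments that the ROI-specific loss emphasises, but hedges
  low-T2 compartments toward the training prior — a small-sample
  effect: with few phantom geometries the conditional-mean prediction
  is loss-optimal, while the per-voxel fitting baseline is unbiased and
  near-optimal on piecewise-constant phantoms. Whether the network's
  test-set mean ROI NRMSE falls below the baseline's therefore depends
  on the draw of held-out geometries; closing the gap reliably requires
  training-set sizes beyond the desk-scale budget. The acceptance suite
  computes this comparison afresh on every run and reports it as
  observed.
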