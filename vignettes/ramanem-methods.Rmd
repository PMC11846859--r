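---
title: "Methods: spatial recognition and semi-quantification of epigenetic marks in Raman hyperspectral maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial recognition and semi-quantification of epigenetic marks in Raman hyperspectral maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanem)
```

## The problem this package addresses

Raman hyperspectral mapping (RHM) rasterises a tissue section into thousands
of pixels, each carrying a full vibrational spectrum in the fingerprint
region (600–1900 cm⁻¹). Because every biomolecular species in the focal
volume contributes bands, a single pixel spectrum is an unlabelled molecular
summary of that location. `ramanem` turns such maps into spatial,
semi-quantitative read-outs of epigenetic state: DNA methylation (DNA-m),
histone lysine methylation (Lys-m) and acetylation (Lys-a), arginine
methylation (Arg-m), and the balance between the right-handed B and
left-handed Z conformations of DNA.

The chain is:

1. **Preprocess** each pixel spectrum: cosmic-spike removal, 3rd-order
   polynomial baseline removal, optional convolutional-autoencoder
   denoising, 0–1 min–max normalisation.
2. **Classify** each pixel as stroma/empty (0), nucleus (1) or cytoplasm (2)
   with a 1-D convolutional network, and keep nuclear spectra for all
   downstream epigenetic analysis.
3. **Correlate** every pixel spectrum against reference spectra of the pure
   species (DNA, CpG-methylated DNA, lysine and its derivatives, arginine
   and its methylated form, B-DNA, Z-DNA). Pearson's R is the default
   metric; the per-map scores are min–max normalised to [0, 1] for heatmap
   rendering.
4. **Call status**: within nucleus pixels, a species is called *positive*
   at a pixel when its Pearson score reaches the 3rd quartile of that
   species' nucleus-pixel score distribution. *Exclusive* spectra for a
   modification are positive for the modification and its base species and
   negative for every other modification.
5. **Analyse**: volcano-plot spectral peak analysis (VSPA) contrasts
   exclusive modified vs base-only spectra per peak (log2 fold change +
   two-sided Mann–Whitney p); group levels are medians of per-spectrum
   scores reported as ratios to control; the Z-DNA score is the group's
   Z/B level ratio relative to control; Kruskal–Wallis with Dunn's post hoc
   and Holm adjustment tests group differences; PCA and t-SNE expose group
   structure.

Because no public tissue maps accompany the method, the package ships a
first-class synthetic generator with known ground truth; every claim the
test suite makes is validated against that ground truth.

## The synthetic-data generator

`make_scene()` lays out connected nuclear blobs (noise-distorted discs) with
a cytoplasm rim inside a stroma background, at a default nucleus pixel
fraction of 0.22. Each pixel holds nonnegative mixing coefficients over a
species library: nuclei mix DNA (coefficient ~1), B-DNA (0.5), Z-DNA
(0.15 × a conformation multiplier), lysine (0.6), arginine (0.4) and
protein; cytoplasm is protein-dominated; stroma is collagen-dominated; all
coefficients carry ±20% per-pixel jitter. A modification's *truth level*
`t ∈ [0, 1]` enters as a multiplier: its coefficient in a nucleus pixel is
`0.6 · t · (base coefficient)`. This makes the truth ordinally recoverable
from correlation scores, which is exactly what the quantification stage
claims to do.

`render_map()` evaluates the mixture on the grid (600–1900 cm⁻¹ at 2 cm⁻¹,
651 points) from Lorentzian band models — the natural Raman lineshape;
Gaussian is available for robustness checks — then adds a random cubic
baseline (coefficients uniform on [0, 0.5] of unit signal, emulating
fluorescence), Gaussian noise (σ = 0.05 of unit signal) and Poisson-count
single-bin cosmic spikes (rate 0.05/spectrum, amplitude 8× the pixel's
maximum signal, so despiking is unambiguous). These defaults were chosen
once as a realistic mid-range operating point for tissue Raman work and are
not tuned per analysis.

What the generator does **not** emulate: instrument response functions,
wavenumber calibration drift, photobleaching kinetics, detector etaloning,
spatial point-spread mixing between neighbouring pixels, and the long-tail
heterogeneity of real tumour histology. Passing tests therefore demonstrate
that the algorithms recover what they claim *under the stated statistical
model*, not that the biological conclusions of any particular tissue study
are reproduced.

## Neural components

No neural-network framework is used: the package implements a minimal 1-D
convolutional engine (im2col convolutions over BLAS matrix products,
nearest-neighbour upsampling, dense layers, Adam, Glorot-uniform
initialisation) so that training is fully deterministic given a seed and
auditable down to the gradient. The backward pass is validated against
central finite differences in the test suite.

**Classifier.** Ten convolutional layers (filters tapering 8→32, kernels
7→3, stride-2 downsampling) followed by four dense layers (256, 64, 16, 3)
with a softmax output; categorical cross-entropy, Adam, batch size 105,
70/30 train/test split, training between 10 and 38 epochs with early
stopping on held-out loss (patience 5) and best-weights restoration. The
published architecture summary fixes the layer counts but not the widths;
the widths here are deliberately narrow because the corpus is separable at
low capacity and the package targets single-CPU training (a full 6,400
spectrum corpus trains in a few minutes).

**Denoising autoencoder.** Nine convolutional encoder layers (three
stride-2 stages to a 16-channel body, 8-channel bottleneck at 1/8
resolution), nine convolutional decoder layers interleaved with
nearest-neighbour upsampling, and a flat sigmoidal output layer mapping
back to the input length, guaranteeing outputs in [0, 1]. Defaults: batch
size 105, 42 epochs, Adam at learning rate 2×10⁻³. Two losses are
available behind a switch: elementwise cross-entropy on 0–1 intensities
(the default) and mean squared error. Hidden activations are `tanh`:
Glorot-uniform initialisation preserves signal variance through an
18-conv-layer stack for tanh-family activations, whereas with relu the
encoder output collapses towards zero at this depth and the decoder
degenerates to predicting the mean spectrum. The learning rate 2×10⁻³ was
chosen from convergence behaviour on synthetic corpora (1×10⁻³ had not
plateaued within the default epoch budget).

The preprocessing order is fixed as despike → baseline → (optional)
denoise → normalise; the denoiser consumes per-spectrum 0–1 scaled input
(its training contract) and its bounded output feeds the final
normalisation directly. Whether denoising runs before or after baseline
removal is genuinely open in the method description; running it after means
the autoencoder only has to learn band structure, not baseline families,
which is the easier and more robust task.

## Numerical choices

* **Baseline removal** uses iterative polynomial fitting with point
  rejection above the fit (clip-to-fit, ≤25 iterations, convergence at
  1e-7 of the intensity scale), followed by a refit on the points sitting
  at the estimated floor, which removes the clip iteration's small downward
  bias near peaks. Plain least squares would track peaks; this scheme is
  exact on peak-free polynomial input and recovers generating cubic
  coefficients closely when peaks are sparse.
* **Despiking** flags bins whose first differences exceed a modified
  z-score (median/MAD) of 8 as an up–down or down–up pair, *and* whose
  entry/exit steps are at least 3× the adjacent background steps. The
  second condition is what separates a one-bin cosmic spike from the apex
  of a genuine band a few bins wide: a resolved band's apex steps are no
  larger than its flank steps, while a spike towers over its
  neighbourhood. Flagged bins are repaired by linear interpolation; end
  bins need one-sided evidence at twice the threshold.
* **Resampling** of references onto the map grid is linear interpolation,
  restricted to the intersection of the grids with the fingerprint window;
  linear is monotone and cannot ring on sharp bands. No extrapolation.
* **Quartile cutoffs** use the linear-interpolation quantile (type 7), the
  most common convention, pinned for reproducibility; ties at the cutoff
  are called positive. Cutoffs are computed per map and per label over
  nucleus pixels only. The correlation-map normalisation runs over all
  pixels of a map (not nucleus pixels only); status calls are unaffected
  because quantile thresholds are rank-invariant.
* **Mann–Whitney** p-values are exact for group sizes ≤ 12 via a
  dynamic-programming enumeration of the midrank-sum distribution
  (equivalent to brute force and correct under ties); larger groups use the
  tie-corrected normal approximation without continuity correction. VSPA
  applies no multiple-testing correction by default, matching the raw
  p < 0.01 rule; Benjamini–Hochberg is available behind a flag.
* **"Peak"** in VSPA means a local maximum of the pooled mean spectrum with
  relative prominence ≥ 5% of its range; an exhaustive per-wavenumber mode
  exists for sensitivity analyses. Fold change is modified-set over
  base-set; zero-denominator positions are excluded and logged.
* **Dunn's post hoc** z uses pooled midranks with tie correction; the Holm
  family is all pairwise comparisons for one modification (one family per
  reported panel), not pooled across modifications.
* **Levels** are medians of per-spectrum scores (means behind a flag);
  spectra, not nuclei or patients, are the analysis unit. Z and B levels
  are both taken over DNA-positive nucleus pixels for comparability.
* **PCA** runs on mean-centred, unscaled normalised spectra (intensities
  share units). **t-SNE** is the exact quadratic algorithm with a
  50-component PCA reduction, perplexity 30, PCA initialisation scaled to
  1e-4, early exaggeration 12 for 250 of 1000 iterations — deterministic
  given its seed.
* **Degenerate inputs**: constant spectra cannot be normalised or
  correlated and raise errors; a correlation map whose scores are all equal
  is flagged and its normalised scores set to 0.5; softmax ties resolve to
  the lowest class index.

## Problem sizes

The test suite and the acceptance script validate at sizes chosen to keep a
single-CPU run comfortable while preserving the statistical structure:
classifier corpora of 2,500–6,400 spectra (the generator reproduces the
10,000–18,000-pixel scale of whole-slide maps when asked), recovery studies
of 20 seeds × three 32×32-pixel groups, 50 null datasets × 200 positions for
test calibration, and autoencoder training corpora of ~400 spectra. These
are the package's own validation conditions, reported as such.

## Known limitations

* Correlation scoring is not spectral unmixing; scores compress additive
  mixtures into similarity and are therefore *semi*-quantitative by design.
  Only ordinal claims about group levels are supported.
* The exclusive-spectra rule discards multi-positive pixels; co-occurring
  modifications at one pixel are out of scope.
* The classifier is trained per corpus (or per map); no transfer between
  instruments or staining protocols is attempted.
* Statistical units are spectra; spatial autocorrelation within a nucleus
  inflates the effective n of the group tests, so p-values on real tissue
  should be read as descriptive rather than confirmatory.
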