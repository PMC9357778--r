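---
title: "Methods: fuzzy segmentation, co-occurrence texture and swarm-tuned classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy segmentation, co-occurrence texture and swarm-tuned classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzymri)
```

# Overview

`fuzzymri` implements a complete desk-scale analogue of a clinical
brain-tumour detection workflow on 2-D grayscale images:

1. **Segmentation** by an improved fast-and-robust fuzzy C-means (IFRFCM):
   morphological reconstruction preprocessing, fuzzy clustering over the
   gray-level *histogram* with a spatial neighbourhood penalty, and adaptive
   Wiener filtering of the fuzzy membership planes.
2. **Texture features** from gray-level co-occurrence matrices (GLCM),
   computed regionally (whole image plus coronal- and sagittal-style
   half-planes).
3. **Classification** by an extreme learning machine (ELM) whose random
   input weights are tuned by particle swarm optimisation (PSO) against a
   validation set.
4. **Diagnostic metrics** — sensitivity, specificity, PPV, NPV and a
   prevalence-weighted accuracy.
5. A **synthetic phantom generator** that makes the whole chain testable
   without clinical data.

This vignette documents the model choices, the tunables and their defaults,
what the synthetic world does and does not establish, and the numerical
conventions.

# The segmentation model

## Objective

Plain fuzzy C-means assigns each pixel $x_p$ graded memberships
$\sigma_{qp} \in [0,1]$ across $C$ clusters with centroids $p_q$, minimising

$$J_0 = \sum_{p=1}^{N}\sum_{q=1}^{C} \sigma_{qp}^{v}\,\lVert x_p - p_q\rVert^2
      + \sum_{p=1}^{N}\sum_{q=1}^{C} G_{pq},$$

where $v > 1$ is the fuzzifier and $G_{pq}$ a *fuzzy factor*: a
neighbourhood penalty

$$G_{pq} = \sum_{r \in N_p,\, r \ne p} \frac{1}{d_{pr}+1}\,
           (1-\sigma_{qr})^{v}\,\lVert x_r - p_q\rVert^2,$$

with $d_{pr}$ the Euclidean distance between pixel centres. The factor
pulls a pixel's membership toward those of its spatial neighbours, weighted
by inverse distance — the mechanism that gives FLICM-style algorithms their
noise robustness. A configuration scale `alpha` multiplies the factor;
`alpha = 0` recovers plain FCM exactly (this limit is what the descent and
histogram-equivalence tests exercise).

## The "fast" reformulation

Because the penalised distances depend on gray value only, the sums over
$N$ pixels collapse onto the $h$ distinct gray levels weighted by their
histogram counts:

$$J_0 = \sum_{q=1}^{C}\sum_{z=1}^{h} n_z\,\sigma_{qz}^{v}\,
        (\xi_z - p_q)^2 + \sum_{q=1}^{C}\sum_{z=1}^{h} \bar G_{qz},$$

so one iteration costs $O(C\,h)$ instead of $O(C\,N)$. The fuzzy factor is
computed on the reconstructed image's pixel grid (memberships looked up by
each neighbour's gray value) and aggregated per gray level by averaging
over the pixels carrying that level; the source material moves the factor
into the gray-level sum without defining this aggregation, so the mean was
chosen as the estimator that keeps $\bar G_{qz}$ on the same scale as a
single pixel's penalty.

The update equations are the standard Lagrangian minimisers with the factor
held fixed:

$$\sigma_{qz} = \Big[\sum_{j=1}^{C}
  \Big(\tfrac{(\xi_z-p_q)^2 + \bar G_{qz}}{(\xi_z-p_j)^2 + \bar G_{jz}}\Big)^{1/(v-1)}\Big]^{-1},
\qquad
p_q = \frac{\sum_z n_z\,\sigma_{qz}^v\,\xi_z}{\sum_z n_z\,\sigma_{qz}^v}.$$

A gray level at exactly zero penalised distance to one or more centroids
splits its membership equally among them; a starved cluster (zero centroid
denominator) is reseeded at the modal gray level with a warning.

## Morphological reconstruction

Before clustering, the image is filtered by opening-by-reconstruction
followed by closing-by-reconstruction with a disk structuring element
(radius 1 by default). The opening removes bright impulses (salt), the
closing dark ones (pepper), and the geodesic reconstruction step restores
the exact shapes of all surviving structures, so edges are not displaced.
Closing alone cannot remove salt noise, which is why the composite filter
is used. The composite is idempotent — asserted in the tests by applying it
twice.

## Wiener filtering of memberships

The final gray-level partition matrix is expanded to the pixel grid (each
pixel inherits its gray value's memberships) and each cluster plane is
smoothed with a local adaptive Wiener filter: windowed mean $\mu$ and
variance $s^2$ (windows truncated at the borders, statistics over the
in-image pixels), noise power $\nu$ estimated as the mean local variance,
and

$$\hat y = \mu + \max(s^2 - \nu, 0)\,/\,s^2 \cdot (y - \mu).$$

Afterwards each pixel's memberships are renormalised to sum to 1 and the
label map is the per-pixel argmax (ties to the lowest cluster index). A
spatial filter needs a pixel layout, so filtering the gray-level matrix
directly is not meaningful; the pixel-domain expansion is the only reading
that makes the operation well defined.

## Tunables

| parameter | default | units / range | why |
|---|---|---|---|
| `clusters` | — | ≥ 2 | number of tissue classes sought |
| `fuzziness` | 2 | > 1 | canonical FCM fuzzifier |
| `alpha` | 1 | [0, 1] | fuzzy-factor scale; 0 = plain FCM |
| `radius` | 1 | pixels | 3×3 neighbourhood, FLICM convention |
| `recon_radius` | 1 | pixels | disk radius; removes 1-pixel impulses |
| `wiener_window` | 3 | odd ≥ 3 | smallest meaningful adaptive window |
| `tol` | 1e-4 | gray levels | max centroid movement at convergence |
| `max_iter` | 100 | — | histogram FCM converges in tens of iterations |

Centroids initialise at evenly spaced positions over the occupied gray
range, jittered by seeded uniform noise. Distribution quantiles were
rejected: when one class dominates (an image background often holds half
the pixels) quantiles place several centroids on the same gray value and
the clustering collapses into a degenerate local minimum.

# Texture features

A symmetric, normalised GLCM is computed at unit distance for the four
standard angles (0°, 45°, 90°, 135°), and six classical statistics are
taken from each: contrast, dissimilarity, energy, homogeneity, entropy and
correlation. The source material never names its feature set; these six are
the standard co-occurrence repertoire. Features are extracted for five
regions — the whole image, top/bottom halves (the coronal front/back
analogue on a 2-D slice) and left/right halves (the sagittal analogue) —
giving a fixed 5 × 4 × 6 = 120-long vector in a documented deterministic
order (region slowest, then offset, then feature).

Quantization: the standalone `quantize()` bins the image's own `[min, max]`
range by default, but `extract_feature_vector()` bins the *representable*
range (0–255 for 8-bit input). Fixed bin edges are essential for a cohort:
with per-image ranges, a bright tumour widens the dynamic range and
*compresses* the healthy-tissue transitions into adjacent bins, inverting
the expected contrast ordering between tumour and clean images. This was
measured, not assumed, and is recorded in the test suite.

# Classification

## ELM

A single-hidden-layer network: hidden activations
$Z_{ni} = b(w_i \cdot x_n + k_i)$ with logistic sigmoid default (tanh and
ReLU selectable), and output weights solved in closed form,
$\beta = Z^{\dagger} d$, via an SVD pseudoinverse with relative cutoff
1e-12. The pseudoinverse gives the minimum-norm least-squares solution and
handles rank deficiency without ridge terms. Targets are one-hot rows;
prediction is the argmax of $Z\beta$. Features are standardised with
training-set statistics stored in the model: random $[-1,1]$ input weights
saturate a sigmoid on raw GLCM feature scales (contrast can be orders of
magnitude larger than energy).

## PSO

Particles minimise a scalar fitness over a box. The inertia rule is

$$w^{n+1} = \Phi(n)\,w^{n} + \beta\,\delta_1\odot(g^*-p^{n})
          + \gamma\,\delta_2\odot(p^*-p^{n}), \qquad p^{n+1}=p^{n}+w^{n+1},$$

with $\delta_1,\delta_2 \sim U(0,1)$ fresh per step, defaults
$\beta=\gamma=2$ and the linear inertia decay
$\Phi(n) = 0.9 - 0.5\,n/\text{max\_iter}$. Positions are clamped to the
box with the velocity zeroed on clamped dimensions — the simplest
deterministic boundary rule. The accelerated rule drops velocity memory:

$$p^{n+1} = (1-\gamma)\,p^{n} + \gamma\,g^* + \beta\,\delta^{n},$$

where the noise $\delta^n$ is scaled by the box width times $0.97^{n}$.
As printed in the source the noise term is unscaled and cannot converge;
geometric annealing is standard accelerated-PSO practice. Defaults
$\beta=0.1$ (stated) and $\gamma=0.7$ (unstated anywhere; a mid-range value
that balances attraction and exploration). Both step functions accept an
injected deterministic randomness source so single steps are exactly
checkable against hand arithmetic.

## PSO-ELM coupling

A particle encodes the flattened input-weight matrix followed by the biases
($H J + H$ dimensions, bounds $[-1,1]$). Its fitness is the
misclassification rate on a held-out validation set of the ELM it induces,
with $\beta$ solved on the training set. Ties are broken toward lower
validation MSE through a bounded smooth penalty
($10^{-3}\,\mathrm{mse}/(1+\mathrm{mse})$, always smaller than one
misclassified sample, so distinct error rates are never reordered). The
hidden-unit count is a fixed hyperparameter per run (default 10–50
depending on the entry point); encoding it in the particle would make the
search space ragged, so a grid over $H$ is the supported route.

# Diagnostic metrics

With diseased/non-diseased counts $M, N, P, Q$ (test-positive and
test-negative within each group):
sensitivity $= M/(M+N)$, specificity $= Q/(P+Q)$, and with prevalence $\pi$:

$$\mathrm{PPV} = \frac{s\pi}{s\pi + (1-sp)(1-\pi)}, \quad
  \mathrm{NPV} = \frac{sp(1-\pi)}{(1-s)\pi + sp(1-\pi)}, \quad
  \mathrm{acc} = s\pi + sp(1-\pi).$$

Prevalence must be supplied explicitly or defaults to the empirical value
from counts, in which case the prevalence-weighted accuracy coincides with
count accuracy $(M+Q)/\text{total}$ — an identity the tests verify
numerically. Accuracy is reported both as a fraction and as a percentage.

# The synthetic world

`generate_phantom()` draws an elliptical head of tissue-A (gray 100) on
background (gray 10) with a few tissue-B blobs (gray 170) and, optionally,
one irregular bright tumour blob (gray 230, radius 5–15% of the image
side, sinusoidally perturbed boundary). Noise kinds: additive Gaussian
(level = SD as a fraction of the 0–255 range), salt & pepper (level =
corrupted-pixel fraction, impulses at 0/255), multiplicative speckle
(level = SD of the multiplier). Everything derives from the seed, so a
phantom is a pure function of its arguments.

The gray levels and geometry were chosen once so that (a) impulse noise
measurably degrades plain FCM while reconstruction-based IFRFCM shrugs it
off, and (b) tumour presence is detectable from co-occurrence texture.
Those are exactly the two claims the pipeline makes, and they are what a
green test establishes — no more. The phantoms have none of the hard parts
of real MRI: no bias field, no Rician noise, no partial-volume effects, no
multi-contrast channels, no anatomical variability. Performance numbers on
phantoms say nothing quantitative about clinical data.

# Numerical conventions and degenerate inputs

- Memberships are renormalised explicitly; columns/pixels sum to 1 within
  1e-9 by construction.
- Argmax label ties go to the lowest cluster index; equal-fitness PSO
  particles keep the first evaluated best.
- The objective trace is recorded after each full update sweep; with the
  fuzzy factor off it is non-increasing (classical FCM descent), with the
  factor on the trace is reported but monotonicity is not guaranteed by
  theory and not asserted.
- Non-convergence at `max_iter` returns the best-so-far state flagged
  `converged = FALSE`, never an error.
- All seeds are plain 32-bit integers; every derived seed stays below
  2^31.

# Known limitations

- 2-D only; volumes would be processed slice-wise and the half-plane
  splits are 2-D analogues of the anatomical planes.
- The fuzzy-factor aggregation to the histogram domain is an average, so
  two images with identical histograms but different spatial layouts can
  cluster identically only in the plain-FCM limit.
- No image formats beyond plain-text PGM are bundled, to keep the package
  free of binary I/O dependencies; matrices are first-class inputs
  everywhere.
- The PSO fitness landscape of an ELM is stochastic-free but piecewise
  constant in the misclassification term; the MSE tie-break supplies the
  gradient-like signal inside the plateaus.
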