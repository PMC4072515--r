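---
title: "Unsupervised discovery of cone spectral classes from response correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised discovery of cone spectral classes from response correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conelearn)
```

## The problem

A retina that gains a new cone opsin — the enabling step for any expansion
of color vision — faces a bootstrapping puzzle: downstream circuitry
receives an unlabeled stream of photoreceptor signals and must somehow
discover that distinct spectral classes exist at all, and which cone belongs
to which class. No gene labels the wires. `conelearn` implements and tests
an unsupervised algorithm that solves this from nothing but the pairwise
Pearson correlations between cone responses to natural-scene patches, and
bundles the simulators (hyperspectral scenes, cone mosaics, spectral
sensitivities, center–surround opponency) needed to exercise it end to end
with no external data.

The statistical leverage comes from two regularities of natural
hyperspectral images: correlation between pixels falls with spatial
distance, and correlation between wavelength bands falls with wavelength
separation. Neighboring cones of the same class therefore correlate
slightly more than neighboring cones of different classes, and that small,
systematic excess is enough to recover the class structure.

## The pipeline

1. **Responses.** Each cone's raw response to a patch is the inner product
   of its spectral sensitivity with the spectrum at its pixel,
   $r = \sum_\lambda S(\lambda)\, I(\lambda)$. A suppressive surround — a
   2-D Gaussian over grid neighbors, normalized to total weight 0.25 — is
   subtracted to mimic lateral antagonism at the first synapse.
2. **Correlation → distance.** The cone×cone Pearson correlation matrix
   $C$ is accumulated over patches in one streaming pass;
   $d = -\log C$ serves as an approximate inter-cone distance.
3. **Embedding.** Non-metric MDS (SMACOF with isotonic disparities,
   minimizing STRESS1 $= \sqrt{\sum(\hat\delta - d_{ij})^2 / \sum
   d_{ij}^2}$, classical-scaling start, one replicate, uniform weights)
   embeds the cones in 3-D. One dimension captures spectral identity, the
   other two the retinal plane.
4. **S cones and rotation.** 2-means clustering isolates the S cones as the
   smaller cluster (their large spectral separation makes them distant from
   everything); the embedding is rigidly rotated so the non-S→S mean vector
   lies along $-e_1$.
5. **Flattening.** The longer-wavelength cones lie on gently curved,
   class-specific sheets. A quadratic surface
   $z_1 = c_0 + c_1 z_2 + c_2 z_3 + c_3 z_2^2 + c_4 z_2 z_3 + c_5 z_3^2$
   is fit to all non-S cones by minimizing the *standard deviation* of the
   perpendicular point-to-surface distances — favoring a surface equally
   distant from every cone over one hugging the majority. Each cone's
   flattened spectral coordinate is its signed distance to that surface,
   negative on the S-cone side.
6. **Classification.** Mixtures of $K = 1, 2, 3$ skew-normal distributions
   are fit to the flattened positions by maximum likelihood; the smallest
   $K$ whose Kolmogorov–Smirnov goodness-of-fit p-value reaches 0.01 is
   selected. Cones take the label of the component with the highest
   weighted density at their position, and components farther from the S
   side are assigned longer peak wavelengths — so the L/M labeling is not
   arbitrary.

Accuracy is reported class-averaged (mean of the per-class correct
fractions), the convention that keeps a 16:1 mosaic from looking good by
majority vote: classifying 354/354 L and 1/22 M cones is 52% balanced, not
94%.

## The synthetic scene generator

The package generates its own hyperspectral stimuli rather than shipping
real databases. A scene is a lognormal texture: independent Gaussian random
fields with a power-law spatial amplitude spectrum
($A(f) \propto f^{-1.5}$ by default) are mixed across the 33 bands
(400–720 nm in 10 nm steps) through a squared-exponential correlation
kernel in wavelength separation (length scale 120 nm), then exponentiated
and scaled. Fields are synthesized on a 4× larger periodic domain,
normalized there, and cropped: scenes behave like windows onto a larger
world, keeping long-range spatial correlation and scene-to-scene luminance
variation, as patch ensembles from real image databases do. With the
default parameters the ensemble pixel correlation at one pixel separation
is ≈0.99, at 20 pixels ≈0.75, with a slowly decaying tail; band correlation
falls smoothly with wavelength separation and is distinctly lower at
320 nm separation than at 0 at any fixed distance.

What the generator does *not* emulate: edges, occlusions and other
higher-order structure of real scenes; realistic reflectance spectra
(bands are jointly lognormal, not material-like); sensor noise and
quantization. Passing tests on these scenes therefore demonstrate that the
algorithm exploits the two correlation regularities correctly — not that it
is robust to everything real databases contain.

## Spectral sensitivities

Cone fundamentals come from the Govardovskii A1 visual-pigment template,
evaluated at a reference peak of 500 nm and shifted rigidly in
log-wavelength to any requested $\lambda_{max}$ (the template validity
window is documented as 400–620 nm on this grid). The log-wavelength shift
is the standard nomogram convention and makes the family exactly
shift-invariant. A fixed analytic lens + macular transmittance curve
(exponential short-wavelength lens density plus a Gaussian macular term at
460 nm) is applied before peak renormalization; it is a stylized standard
observer, not a tabulated one, and can be switched off. Units are quantal
throughout — only correlations matter downstream, so any per-cone affine
scaling is irrelevant.

Typical-observer peaks are 558.9 (L), 530 (M) and 420.7 nm (S); anomalous
trichromats are modeled by moving the M peak toward L (555 nm leaves a
3.9 nm separation), tetrachromats by adding a fourth class at 545 nm.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| mosaic side | 20 cones | 400 cones: large enough for stable correlation estimates, small enough for desk-scale runs |
| S fraction | 6% | typical foveal proportion; placed quasi-regularly with min spacing 2.5 cone units |
| surround σ / weight / support | 2.0 cones / 0.25 / radius 5 | weight sum 0.25 is the normalization constant of the suppressive surround; σ and support are config defaults |
| patches | 1e5 | learning is near-asymptotic well below the 2e6 used in full-scale studies; 1e5 keeps a run ~30 s |
| correlation floor | 1e-6 | $-\log\rho$ is undefined for $\rho \le 0$ (possible with surrounds); clamping is logged |
| NMDS | 3-D, ≤300 iter, tol 1e-6 | STRESS1 with classical start; keep-best guard stops on any stress increase, so the recorded history is non-increasing |
| KS criterion | p ≥ 0.01, K ≤ 3 | smallest-K-not-rejected selection |
| mixture restarts | 20 | quantile-split initialization plus seeded jitter; scales floored at 1e-4 × range |

## Numerical choices

* **Perpendicular distances.** Point-to-surface distance uses a vectorized
  Newton solve of the foot-point normal equations (≤25 damped iterations),
  falling back to the dimension-1 residual where the solve fails; fallbacks
  are counted and reported.
* **Surface fit.** The sd-of-distances objective has nearby local basins,
  so the fit multi-starts Nelder-Mead (8 seeded starts around the
  least-squares quadratic regression, each polished by a restart). This
  makes the fit invariant, in practice, to rotations within the
  (dim 2, dim 3) plane.
* **Skew-normal CDF.** Owen's T by fixed 64-node Gauss–Legendre
  quadrature; shapes are bounded at |α| ≤ 50 during fitting. Near α = 0
  the direct parametrization has a flat likelihood ridge, so point
  estimates of α on nearly-normal data are noisy even when the fitted
  distribution is excellent; tests assess the reduction case by likelihood
  ratio rather than by the raw estimate.
* **KS p-values** use the asymptotic Kolmogorov distribution with no
  correction for estimated parameters — deliberately anti-conservative,
  and part of the selection procedure's definition.
* **Ties** in the isotonic regression are broken by index; classical-MDS
  axis signs are fixed by making the first nonzero loading positive;
  exact density ties in classification go to the longer-wavelength
  component.
* **Determinism.** Every stage seed derives from one master seed; identical
  configurations reproduce reports exactly.

## Design choices that were genuinely open

* **Tritanope mosaics** (no S cones): the automated rotation needs the S
  anchor, so it is skipped and a manual rotation hook (user-supplied
  orthogonal matrix plus a sign convention for the flattened axis) is
  provided instead, matching how such embeddings are oriented by hand.
* **Cone-selective surrounds** draw only on other-class longer-wavelength
  neighbors (L↔M; S surrounds on all non-S classes); cones with no
  eligible neighbor legitimately have no surround. Boundary cones
  renormalize their available weights to the full 0.25 so the
  normalization contract holds everywhere.
* **One joint surface** is fit to all non-S cones rather than per class;
  with extreme class ratios it can over-represent the numerous class —
  a known failure mode surfaced through per-class residual diagnostics
  rather than hidden.
* **Noise convention:** the noise sd is a fraction of the per-patch mean
  response over cones by default, with the grand-mean alternative as a
  switch.
* **Patch size** equals the mosaic footprint (side × stride); stride 2 or
  4 implements coarser cone spacing relative to the image scale.

## Scales used by the test suite

The packaged tests run the full pipeline at 1e5 patches on 20×20 mosaics
for the detection checks (dichromat → K=1, trichromat → K=2 with balanced
accuracy ≥ 0.95, tetrachromat → K=3), and 3e4-patch runs on 80-px scenes
over ten seeds per arm for the direction-of-effect comparisons (optical
blur σ = 4 px does not hurt; cone-selective surrounds do no better than
uniform; a 3.9 nm L–M separation does no better than 28.9 nm). These sizes
are the package's documented desk-scale study conditions; the NMDS oracle
suite uses ≤12-point instances where an exhaustive multi-restart reference
is computable.

## Known limitations

* Synthetic scenes carry only second-order spatial/spectral structure;
  absolute accuracies here need not match those obtained on real
  hyperspectral databases, though every detection and direction-of-effect
  claim tested is reproduced on the synthetic ensemble.
* The KS selection is anti-conservative (parameters estimated from the
  same data), inherited by design.
* The spatial arrangement recovered in dims 2–3 is approximate; the rigid
  alignment residual is reported in cone units after a global scale
  normalization, since MDS units are arbitrary.
* K is capped at 3 longer-wavelength classes; hexagonal mosaics, optical
  point-spread beyond Gaussian blur, and photon noise are out of scope.
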