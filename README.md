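# conelearn

How could a visual system discover, with no labels, that its retina
contains distinct cone spectral classes — and which cone is which? The
enabling step in the evolution of color vision is the expression of a novel
opsin, but a new cone class is useful only if downstream circuitry can tell
its signals apart from everyone else's. `conelearn` implements an
unsupervised algorithm that answers both questions from nothing but the
pairwise correlations between simulated cone responses to natural-scene
patches, together with everything needed to test it end to end: a synthetic
hyperspectral scene generator, cone mosaic construction, nomogram-based
spectral sensitivities, and center–surround opponency.

It is aimed at computational neuroscientists and vision scientists studying
sensory coding, receptor mosaics, and unsupervised structure discovery in
neural populations.

## The algorithm

Given a mosaic of cones responding to image patches with
`r = Σ_λ S(λ) I(λ)` (minus a Gaussian surround normalized to total weight
0.25), the pipeline:

1. accumulates the cone×cone Pearson correlation matrix `C` over patches;
2. embeds `d = −log C` in 3-D by non-metric MDS (SMACOF with isotonic
   disparities, STRESS1 criterion, classical-scaling start);
3. finds the S cones as the smaller of two k-means clusters and rotates the
   embedding so the spectral axis is dimension 1;
4. flattens the curved sheets on which the longer-wavelength cones embed,
   via a quadratic surface fit that minimizes the *standard deviation* of
   the perpendicular point-to-surface distances, yielding a signed 1-D
   spectral coordinate per cone (negative on the S side);
5. fits mixtures of K = 1, 2, 3 skew-normal distributions to those
   coordinates and selects the smallest K not rejected by a
   Kolmogorov–Smirnov test at p ≥ 0.01;
6. labels each cone by the highest-density component, ordering components
   so that farther from the S cones means longer peak wavelength.

Accuracy is reported class-averaged (the mean of per-class correct
fractions): 354/354 L cones plus 1/22 M cones is 52%, not the 94% a raw
fraction would suggest.

## Worked example

A typical trichromat: 20×20 mosaic, 6% S cones, L:M ratio 1:1, peaks at
558.9/530/420.7 nm, uniform surround, 100,000 synthetic-scene patches.

```r
library(conelearn)
cfg <- run_config(n_patches = 1e5, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> cone-class discovery report
#>   mosaic: 20x20, true longer-wavelength classes: 2
#>   selected K = 2 (correct)
#>   balanced accuracy = 100.0%, overall = 100.0%
#>   per-class: M 100.0%, L 100.0%
#>   S-cone identification accuracy = 100.0%
#>   embedding STRESS1 = 0.0151, spatial RMS residual = 1.29 cone units
print(report$artifacts$selection)
#> selected K = 2 (criterion p >= 0.01)
#>  K       D      p
#>  1 0.31737 0.0000
#>  2 0.02741 0.9401
```

Reading this: the algorithm, shown only response correlations, correctly
rejected the one-class description of the longer-wavelength cones (KS
p ≈ 0 at K = 1), accepted two classes (p = 0.94), identified all 24 S
cones, and assigned every L and M cone its true class; embedding
dimensions 2–3 also recover each cone's retinal position to within about
1.3 cone spacings after rigid alignment. A dichromat config
(`classes = list(cone_class("L", 558.9)), ratio = 1`) yields K = 1; a
tetrachromat (`L/A/M` at 558.9/545/530, ratio 1:1:1) yields K = 3.

A thin CLI over the same functions lives at `inst/cli/conelearn.R`
(`run`, `scenes`, `mosaic`, `spectra` subcommands).

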