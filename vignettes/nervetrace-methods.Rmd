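---
title: "Methods: synthetic nerve phantoms, encoder-decoder segmentation and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nerve phantoms, encoder-decoder segmentation and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transverse B-mode ultrasound of the wrist shows the median nerve as a dark
(hypoechoic) oval bounded by a bright (hyperechoic) epineurium rim, embedded
in speckled soft tissue. Clinical work on carpal tunnel syndrome relies on
morphometry of that cross-section — the cross-sectional area (MNCSA), the
traced circumference, and the longest diameters in the radial–ulnar (D1) and
dorsal–palmar (D2) directions — which is usually obtained by manual tracing.
`nervetrace` implements the full computational pipeline for studying whether
encoder–decoder convolutional networks can replace the manual step: it
generates controllable synthetic stand-ins for the ultrasound frames, trains
a U-Net and a SegNet on them, and quantifies both segmentation quality and
the agreement between "manual" and network-derived morphometry.

Real wrist recordings are not redistributable, so the package's phantom
generator is a first-class, tested component rather than a fixture: every
phantom carries its generating parameters, which makes the true morphometry
of each image exactly recoverable.

## Phantom model

A phantom is defined by `phantom_spec()`: an ellipse (semi-axes $a, b$,
rotation, centre) with a rim of configurable thickness, three mean
echogenicity levels ordered interior < background < rim, an isotropic
Gaussian outline blur $\sigma$, and multiplicative gamma speckle with mean 1
and variance $1/k$ (shape $k$). The rendered intensity is

$$ I = \mathrm{quant}_{8}\big(\mathrm{clip}_{[0,1]}\big( (E * G_\sigma)\cdot S \big)\big), $$

where $E$ is the piecewise-constant echogenicity map, $G_\sigma$ a Gaussian
kernel (via EBImage), and $S$ the speckle field. Gamma speckle with mean one
is the standard proxy for fully developed B-mode speckle; its shape
parameter is left configurable because the source images' noise statistics
are unknown. The ground-truth mask contains exactly the pixels whose centres
lie inside the unblurred ellipse: blur and noise degrade the *image*, never
the anatomical truth, mirroring a fixed anatomy under degraded imaging.

`generate_dataset()` samples covariates uniformly from `phantom_ranges()`.
Defaults (at the 300-pixel rendered geometry) were calibrated once,
qualitatively, against published example frames: semi-major axis 28–48 px
(the nerve spans roughly a quarter to a third of the cropped field of view,
area about 2.5–5% of pixels), aspect ratio 1.2–2.4, rotation ±25°, rim
2–4 px, blur 0–1.5 px, speckle shape 4–12. A configurable fraction
(default 20%) is drawn from a *hard stratum* — aspect ratio 2.5–3.5 with
blur 2–4 px — emulating the elongated, blurred appearances on which
segmentation is known to degrade. `phantom_ranges(scale =)` rescales all
geometric quantities so the same relative anatomy can be rendered into
smaller frames.

What the phantoms deliberately do not model: acoustic physics (no
point-spread function or RF simulation), neighbouring structures (tendons,
ligament, bone shadows), attenuation gradients, or operator-dependent probe
artefacts. Passing tests on phantoms therefore demonstrates that the
*pipeline* — training, metrics, morphometry, statistics — behaves correctly
and that the networks can exploit rim/interior contrast; they do not certify
performance on clinical images.

The simulated manual annotation (`perturb_annotation()`) displaces the mask
boundary by a smooth random radial field (low-order Fourier series in the
polar angle, RMS equal to `magnitude`, including a constant term so each
"rater" can be systematically tight or loose). The warp samples the source
mask bilinearly so the displaced outline stays as smooth as the field
itself; the result is reduced to its largest connected component.

## Dataset preparation

`split_dataset()` partitions identifiers as `round(3n/4)` training,
`round(n/12)` validation, remainder test — 450/50/100 at n = 600 — with the
permutation drawn from a seed. The rounding order is a package choice; only
the n = 600 case is externally pinned. `augment_flips()` adds exactly one
flipped copy per training image (vertical, horizontal or both, chosen at
random per image), doubling 450 to 900; sampling *with* replacement was the
alternative reading, rejected because the doubling is exact. Frames are
resampled bilinearly and masks by nearest neighbour (so they stay binary);
intensity normalisation to [0, 1] happens at model ingestion.

## Architectures

Both networks share the encoder: `depth` stages of two same-padded 3×3
convolutions with ReLU followed by 2×2 stride-2 max-pooling, channel widths
doubling from `base_channels`. At the defaults (256-px input, depth 5) the
encoder bottoms out at an 8×8 map. The U-Net decoder mirrors the encoder
with learned 2×2 transposed convolutions and skip concatenations and adds a
bottleneck block; the SegNet decoder instead unpools through the argmax
indices recorded by each pooling layer and carries no skips, so it always
trains fewer parameters at an identical configuration. A 1×1 convolution
and sigmoid produce per-pixel probabilities; masks are cut at probability
0.5 (the binarisation rule is a package choice).

Choices where the published description is ambiguous or silent: kernel
sizes follow the canonical 3×3-convolution / 2×2-pooling layout (the
source's "2×2 convolution and 3×3 max-pooling" is inconsistent with its own
256 → 8 contraction over five stages and is treated as a transposition);
same padding throughout (required for an exact 256→256 round trip); no
batch normalisation or dropout; He-normal initialisation from a seed.

The engine itself is written in R: feature maps are (H·W)×C matrices,
convolutions are im2col gathers followed by one BLAS multiply, and the
backward pass is hand-derived and verified against central differences in
the test suite.

## Training

`train_segmodel()` minimises mean binary cross-entropy (probabilities
clipped at 1e-7) with Adam (defaults lr 0.001, β₁ 0.9, β₂ 0.999, ε 1e-7 —
only the optimiser's identity is externally given). Each epoch shuffles the
training set from the seed. "Divided into five batches" is honoured by
`n_batches = 5` (batch size ⌈n/5⌉); the alternative reading — mini-batches
of five images, giving many more optimiser steps per epoch — is available
through `batch_size` and is what the package's own study-scale runs use,
since five updates per epoch are far too few for from-scratch convergence
at desk scale. There is no early stopping and no schedule: exactly
`epochs` epochs (default 20), validation loss computed without updates.
Training aborts with a named epoch on non-finite loss.

## Evaluation metrics

Per image, from pixel confusion counts: precision TP/(TP+FP), recall
TP/(TP+FN), DICE 2TP/(2TP+FP+FN) (the harmonic mean of precision and
recall) and IoU TP/(TP+FP+FN). Degenerate conventions (documented and
tested): an empty prediction has precision 1 against an empty truth and 0
otherwise, symmetrically for recall; DICE and IoU of two empty masks are 1.
Summaries average per-image metrics (mean ± sample SD, n−1), not pooled
pixels — the alternative was rejected because the reported study statistics
are per-image means. The IoU distribution uses ten width-0.1 bins with the
mode reported as the left edge of the fullest bin (ties to the lowest bin).
No connected-component cleaning is applied before metrics; morphometry
applies it separately.

## Morphometry

`measure_mask()` reduces a mask to its largest 8-connected component,
counts pixels for the area, traces the boundary with Moore-neighbour
tracing (the automated analogue of manual outlining) and takes the polygon
perimeter — steps of 1 or √2 px — as the circumference. The minimum-area
bounding rectangle of the outline comes from the convex hull plus rotating
calipers (the optimal rectangle has a side collinear with a hull edge); D1
is the side within ±45° of the image horizontal, D2 the perpendicular one,
with ties at exactly 45° resolved to the longer side.

Coordinates are pixel centres, so an axis-aligned W×H rectangle measures
(W−1)×(H−1) across; `pad = TRUE` adds one pixel per diameter when
area-consistent sizing (d1·d2 ≥ area) is wanted. Numerical caveats,
verified in tests: digitised minimum rectangles are flip-invariant only to
about half a pixel, and for near-circular shapes (aspect below ~1.5) the
rectangle's orientation — hence the D1/D2 assignment, not the side lengths —
is ill-conditioned. The staircase perimeter of a digitised disc exceeds the
ideal circumference by a few percent; the isoperimetric inequality is
asserted with a 5% discrete tolerance. With the default `mm_per_pixel = 1`
all quantities are in pixel units; no physical calibration is assumed.

## Agreement statistics

`spearman_corr()` ranks with midranks and takes the Pearson correlation of
ranks; the two-sided p-value uses the t approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ with n−2 df (exact permutation is kept as a
test oracle for tiny n). Magnitudes are banded weak (0.2–0.39), moderate
(0.4–0.59) and strong (0.6–0.79) on |r_s|; values in the gaps or outside
the bands report `"other"`. `two_sample_t()` defaults to the unpaired
pooled-variance Student's test (a paired option exists; the unpaired form
is the default because the source analysis names only "Student's t-test").
`bland_altman()` takes differences as reference − test, so a positive mean
difference means the test method underestimates; limits of agreement are
mean ± 1.96 SD with the achieved coverage reported.

## The orchestrated study and problem sizes

`run_study()` chains generate → split → resize → augment → train (both
architectures) → predict → metrics → morphometry → agreement from a single
`study_config()`; every stage has a named seed derived from the master
seed, so a configuration reproduces its outputs bit for bit. The defaults
state the full study conditions (600 images, 256-px input, depth 5, base
16, 20 epochs). The package's own executable experiments — the end-to-end
test and `scripts/acceptance.R` — run a reduced instance chosen once from
arithmetic cost estimates: 60 phantoms rendered at 128 px, 64-px input with
3 pooling stages (the 8×8 bottleneck is preserved), 8 base channels,
20 epochs with mini-batches of 5, and a 1-px simulated-annotation
displacement (scaled with the input). At that scale the trained U-Net
reaches a mean IoU around 0.9 and consistently outperforms SegNet, easy
renders outscore the elongated+blurred stratum for both models, and every
test IoU is positive — the same qualitative structure as the full-scale
study, at desk-scale cost.

## Known limitations

Phantoms are single-structure and noise-stationary; conclusions about
clinical images require real data. The CNN engine is CPU-bound R and
practical only at reduced resolution; the full 256-px configuration is
exercised for its shape contracts, not trained in the tests. Circumference
comparisons inherit the digitised-perimeter bias, and D1/D2 orientation is
unstable for near-circular nerves. Spearman p-values rely on the t
approximation, which is inaccurate below n ≈ 10.
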