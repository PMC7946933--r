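---
title: "Methods: signal isolation and cell scoring in multiplex immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal isolation and cell scoring in multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic benchmarks demonstrate. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Signal model

A raw channel raster is modeled as

    I^c(x, y) = I_s^c(x, y) + I_B^c(x, y)
                + sum_{c'} alpha_{c'} I^{c'}(x, y)
                + sum_{c''} beta_{c''} I^{c''}(x, y) + noise

where `I_s` is the specific immunolabeling signal of interest, `I_B` a
background of tissue autofluorescence modulated by non-uniform illumination
and photobleaching, `alpha` fractional spectral bleed-through from other
channels of the stack, and `beta` fractional molecular cross-labeling
(non-specific antibody binding, hence object-borne). Two standing
assumptions, inherited from optimized staining protocols, license the whole
correction strategy: specific signal is brighter than background, and
cellular objects have a characteristic spatial scale band
`[sigma_min, sigma_max]` that the background does not share.

## Registration

Rounds are aligned to a reference round by a single affine transform (slides
hold the tissue nearly rigid between rounds). DAPI is re-imaged every round
precisely to provide landmarks.

*Keypoints.* Oriented FAST-9 corners with intensity-centroid orientation and
steered 256-bit BRIEF descriptors, extracted per window of an 8 x 8 grid
(500 keypoints per window cap). One deliberate departure from the usual
descriptor geometry: the BRIEF sampling footprint is wide (offsets up to
24 px, drawn with SD 8 px) relative to a nucleus. Individual nuclei are
featureless round blobs; a descriptor confined to one nucleus is ambiguous,
while a wide footprint encodes the local *constellation* of nuclei, which is
unique. With the narrow classical footprint the mutual-match inlier fraction
on synthetic DAPI scenes was below 20%; with the wide footprint it is
typically above 80%.

*Matching and estimation.* Mutual nearest neighbors under Hamming distance
with a 0.9 ratio test; RANSAC over 3-point minimal samples (2000
iterations, 2 px inlier tolerance, 20-inlier minimum consensus), then a
least-squares refit on the consensus set, which is what delivers sub-pixel
accuracy — the tolerance only gates membership. RANSAC runs globally on
pooled windowed keypoints: windows accelerate extraction, but a global
consensus uses the full mosaic's geometry. Warping is inverse-mapped
bilinear interpolation with zero fill outside the field.

## Intra-channel background (ASF)

The background estimate is an alternating sequential filter: grayscale
opening then closing with disk structuring elements, radii doubling from
`sigma_min` to `sigma_max` (e.g. 2, 4, 8, 16; `sigma_max` is appended when
not itself a doubling step). Opening-first targets bright structures —
consistent with "signal brighter than background". The sigmas are *radii*
in pixels. Defaults `sigma_min = 2`, `sigma_max = 16` cover nuclei of radius
4–7 px and somata up to ~14 px at 0.325 um/px; objects inside the band are
excluded from the background (hence preserved by subtraction), while folds
and sediment wider than `2 * sigma_max` remain in the background and are
removed. Negative residuals are clipped to zero (fluorescence is
non-negative). Grayscale morphology runs on the [0, 1] scale internally.

## Sparse inter-channel unmixing

Bleed-through donors are discovered by nonnegative l1-regularized least
squares of the target on the other channels over a user ROI chosen to
contain background, autofluorescence and bright specific signal. Three
estimator details matter and are deliberate:

1. **Offset term.** The fit includes an unpenalized nonnegative intercept.
   Residual background after ASF correction is small but spatially
   correlated across channels (shared autofluorescence texture); without an
   offset that shared level is absorbed into the donor fractions as a
   systematic positive bias.
2. **Donor-object pixels only.** The regression rows are restricted to
   pixels bright in at least one *donor* channel. Pixels bright only in the
   target carry its own specific signal, which no donor can explain, and
   would otherwise swamp the fit; background-dominated pixels would couple
   channels through the shared residual texture. Donors with no detectable
   ROI signal (no object-like contrast, or a signal scale under 5% of the
   stack's) are unidentifiable as bleed sources and are excluded.
3. **Sparsity constant by cross-validation.** `gamma` defaults to 5-fold CV
   on the ROI pixels with the one-standard-error rule (strongest sparsity
   within one SE of the minimum CV error); `gamma = 0` reduces to
   nonnegative least squares.

Cross-labeling donors come only from the user-declared set `E` and are
excluded from the automatic candidates. The joint model is refit by
box-constrained least squares (fractions in [0, 0.999]) on the active set.
The budget `K` (default 3) caps the number of active contaminant channels;
on overflow the K largest fitted fractions are retained and the model
refit. The literal reading of the constraint — active fractions summing
exactly to K — is dimensionally odd for fractions below 1 but available via
`literal_sum_k = TRUE`, which rescales the active fractions.

Nuclear counterstains (DAPI, pan-histone) are excluded from stack unmixing
by default: they are imaged in every round for registration, and they
co-localize with every nucleated marker, so a regression would read genuine
nuclear co-localization as contamination. Identifiability on real panels
has the same character: two markers expressed in the same compartment of
the same cells cannot be separated by pixel regression, which is exactly
what the declared set `E` is for.

*Solver.* Projected coordinate descent (closed-form coordinate updates with
clipping). `glmnet` is used in the test suite as an independent
cross-check of the solver, never as the implementation.

## Nucleus detection

The fused nuclear image is the clipped sum of DAPI and pan-histone: DAPI
labeling varies regionally and drops out for many cells; pan-histone drops
out in complementary territory; the sum reveals nuclei more reliably than
either alone. The classical bootstrap segmenter seeds a watershed-style
region growing with multiscale LoG blob maxima inside a foreground mask.
The foreground cut is *half* the Otsu threshold: after correction the
background sits near zero while a nucleus with one dropped-out stain sits
well below the bright mode, and plain Otsu splits the bright mode and
discards exactly the dim nuclei the fusion strategy exists to keep.

The learned detector is a two-stage region-proposal design at desk scale:
blob proposals (stage one) re-scored by a ridge-regularized logistic head
over two-channel patch features (stage two), trained on auto-generated
labels with random negative boxes added (clean scenes yield too few
negative proposals otherwise). Large rasters run tile-by-tile (512 px
tiles, 64 px overlap); thresholds are computed globally so tiled and
whole-image inference agree exactly, boxes touching interior tile borders
defer to the neighboring tile that contains them fully, and residual
duplicates fall to NMS (IOU 0.3). Evaluation uses greedy score-ordered
one-to-one matching at IOU 0.5, ties broken by higher IOU then lower id;
the ROC sweeps the detection score, with the false-positive rate normalized
to the total false-detection count and the curve extended horizontally when
recall saturates below 1 (missed objects are never recovered by lowering
the threshold); AUC is trapezoidal.

## Capsule cell typing

Patches of 32 x 32 px (downsampled 2x) around each detection, over the five
type-marker channels, feed a capsule network: a learned linear feature
layer into 16 primary capsules of dimension 8 (squashed), routed by
dynamic routing (3 iterations) into one 16-dimensional capsule per class.
The squashing `v = |s|^2 / (1 + |s|^2) * s / |s|` bounds every class
vector's length in [0, 1]; the length is the type's existence probability,
and a cell with all lengths below 0.5 is assigned to the unknown class.
Training minimizes the margin loss with `m+ = 0.9`, `m- = 0.1`,
`lambda = 0.5` via mini-batch Adam; routing coefficients are treated as
constants during backpropagation (standard practice for small capsule
stacks). The shared-transform primary-capsule layout is the efficiency
variant: one transform matrix per (primary, class) pair shared across the
batch.

Three training details are the package's own choices, documented because
they shape behavior:

- **Gaussian center prior** on the input patch (SD = patch/3): the cell's
  own territory dominates over encroaching neighbors in crowded fields —
  without it, a neighboring endothelial RECA1 ring crossing the patch
  periphery produces spurious endothelial calls.
- **Absent-class examples** (15% of each batch, dark noise-only patches)
  train all lengths low off-manifold, which the open-set threshold relies
  on; the margin loss supports all-absent targets natively.
- **Crowded-field augmentation** (`aug_frac`): a fraction of training
  patches is overlaid with another corpus patch shifted to the periphery,
  label unchanged — teaching rejection of neighbor signal.

Training corpora are built per type from the detections with the highest
mean defining-marker expression in-box (`training_top_n`, default 5000 at
production scale; benchmark scenes use what the scene offers), ties to the
lower cell id. The intensity baseline thresholds the population histogram
of in-box means per marker (valley estimator, Otsu fallback) and takes the
largest positive margin in population-SD units; its measurement box is
enlarged 1.5x because nucleus boxes miss somatic and membrane markers
entirely (an endothelial nucleus box contains none of the RECA1 ring). The
capsule-vs-baseline comparison on overlap-heavy scenes is assessed as mean
accuracy over several seeded scenes — single-scene differences of one or
two cells are noise.

## Compartments

8-connectivity throughout (membrane areas depend on it). Nucleus and soma
come from type-specific marker channels (rule table: Sox2/S100b/GFAP for
astrocytes, IBA1 for microglia, NeuN + MAP2 for neurons, Olig2 + CNPase for
oligodendrocytes, RECA1 as endothelial membrane), thresholded globally,
taking the connected component at the detection centroid; a cell with no
nuclear foreground receives a box-inscribed ellipse (flagged), an empty
soma degenerates to the nucleus (flagged). Containment is enforced by
intersection, so `|soma| = |nucleus| + |cytoplasm|` holds exactly.
Processes: bimodal binarization, soma removal, Zhang–Suen thinning, then
synchronous multi-source BFS along the skeleton from somata grown by 2 px
(thinning can retract the skeleton a pixel or two off the soma edge);
bridges between two somata split at the midpoint, ties to the lower id.
Directional ratios cast 16 orientations over 180 degrees and score each
pixel min/max chord length; chords shorten near any boundary, so the
soma/process split grows the high-ratio core geodesically by 3 px to
reclaim the soma's boundary ring. Membranes: thresholded marker pixels
assigned to the nearest cell, or the 1-px dilation ring of the compartment
union (a square of side n gains 4n + 4 pixels).

## Phenotyping and quantification

Compartment means per (marker, compartment); empty compartments are NaN,
never zero. Boolean calls threshold the population histogram of the
configured compartment's means — valley-between-modes when bimodality is
detectable (two density modes with a valley at least 15% below the lower
peak), else Otsu, else manual override; thresholds are logged so every call
is reproducible from the means table. Neuronal subtypes follow
exactly-one-positive logic with margin resolution and an ambiguity flag on
multi-positives; PCNA (nucleus) and CC3 (soma) give independent
proliferation/apoptosis flags. Region summaries assign each cell by the
atlas label under its centroid; densities are counts per 10^6 px^2 of
region area, and the global composition percentages over mutually
exclusive types plus Unknown sum to 100.

## The synthetic scene generator

The generator is first-class, tested code and the oracle for everything
else. It renders typed cells (elliptical nuclei and somata; branched
random-walk arbors for neurons, astrocytes, oligodendrocytes, microglia;
elongated membrane-dominant endothelial shapes), with per-cell lognormal
positive expression (median 15,000 16-bit units, sdlog 0.25) against
near-zero negatives — the bimodal histograms the phenotyping stage assumes.
DAPI and pan-histone drop out regionally (a smooth field splits the scene
into DAPI-weak vs histone-weak territory; per-cell dropout to 5% intensity,
expected fraction 0.2 by default). Background is autofluorescence texture
(smooth random field) times a radial illumination profile (amplitude 0.3)
times a photobleaching gradient across rounds and the acquisition axis
(0.2); sensor noise is Gaussian (SD 50). Bleed-through adds
`alpha * I_s^{donor}` uniformly; cross-labeling adds `beta * I_s^{donor}`,
which is object-borne by construction since `I_s` lives only on objects.
Rounds can be warped by small affines. The pre-noise reconstruction
identity `raw = I_s + I_B + mixing` is exact by construction and asserted
in tests.

Default study conditions: 512 x 512 px at 0.325 um/px, 150 cells, type
proportions (neuron 0.35, astrocyte 0.25, oligodendrocyte 0.20, microglia
0.12, endothelial 0.08), nuclear radii 4–7 px, PCNA+ fraction 0.10, CC3+
fraction 0.05. Dropout rates are not quantified in the field's protocols;
0.2 is a deliberately harsh setting that makes the fusion property visible.

**What passing tests do not show.** The generator's cells are smooth
parametric shapes with spatially uniform expression per compartment; real
tissue has texture, anisotropic point-spread, chromatic shifts, partial
3-D overlap through the section thickness, and far more morphological
variability. Synthetic benchmarks validate the *logic* of each stage —
recovery of planted parameters, orderings (fused > single-channel AUC,
capsule >= intensity baseline in crowded fields), and invariants — not
performance on real mosaics. Bleed-through recovery additionally requires
identifiability: an ROI (or scene) where donor markers are not genuinely
co-localized with the target, which is the same condition the ROI-selection
step imposes in practice.

## Problem sizes

Test and acceptance scenes run at 256–512 px with 25–230 cells, training
corpora at ~25–40 cells per type and 20–25 epochs — sizes chosen so the
whole suite exercises every stage, including detector and capsule training,
in a few minutes on one CPU core. The architecture is size-independent:
tiled detection and per-window keypoint extraction exist precisely to scale
to whole-slide mosaics.

## Known limitations

- The unmixing estimator reads genuine spatial co-localization as mixing
  when donors overlap the target's own objects; declared `E` pairs and ROI
  choice are the mitigations, as in practice.
- The learned detector is a proposal re-scorer: it cannot find an object
  the blob stage never proposed (dense clusters degrade the proposal
  stage, which is measured in the tests).
- Capsule training at desk scale uses a linear feature layer rather than a
  convolutional stack; on real imagery a deeper front end would be needed.
- FCS export writes a minimal standard-conformant FCS 3.0 container
  (32-bit floats, list mode); category columns are stored as integer codes.
- Lazy tiled access tiles the in-memory raster; strip-level lazy TIFF IO is
  not provided by the available readers.
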