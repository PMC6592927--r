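---
title: "Rotation-invariant texture classification of EmA immunofluorescence images"
author: "emaclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant texture classification of EmA immunofluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaclass)
```

# The problem

The IgA-class endomysial antibody (EmA) test is an indirect
immunofluorescence assay on umbilical-cord tissue sections, read under the
microscope into four classes: **I** positive (bright staining of reticulin
fibers in vascular walls and of Wharton's jelly), **II** negative (dim,
unstructured field), **III** IgA deficient (near-dark field regardless of
disease status), and **IV** equivocal (weak or partial staining an expert
cannot call). The reading is subjective and requires an experienced
evaluator; `emaclass` implements an automatic reading as a texture
classification problem: staining class is carried almost entirely by the
*texture statistics* of the green fluorescence channel, not by where on the
slide the structures sit or how the section happens to be oriented.

That last point drives the whole design: a tissue section can lie at any
rotation, so the descriptor must be rotation invariant.

# Preprocessing

Slides are acquired with the red and blue channels suppressed, so colour
sources are reduced to the green plane; integer intensities are rescaled to
$[0,1]$ by the dtype maximum. Before feature extraction, local contrast is
boosted by **unsharp masking**

$$I' = \mathrm{clip}\!\left(I + a\,(I - G_\sigma * I),\ 0,\ 1\right)$$

with defaults $\sigma = 1$ px and $a = 1$. Unsharp masking was chosen because
it is the standard edge-contrast enhancer and — with a symmetric kernel and
mirror boundary padding — commutes with 90-degree rotation, so it cannot
break the descriptor's invariance. Mirror padding also makes constant images
exact fixed points (tested). `amount = 0` is an exact identity, providing a
clean off-switch.

# The descriptor

## Local binary patterns

At radius $r$, each pixel $p$ receives the 4-bit code
$$c_r(p) = \sum_{i=0}^{3} 2^i\,\big[\,I(p + r\,e_i) - I(p) \ge 0\,\big],$$
with $e_0,\dots,e_3$ the East, North, West, South offsets. Ties count as 1,
stated explicitly so that flat regions give the stable code 15 rather than
noise-driven codes. The 4-neighbour "+" pattern at integer radii needs no
interpolation and keeps the code-pair space at $16 \times 16$, which is what
makes the co-occurrence statistics below tractable.

## Co-occurrence of adjacent codes

Texture is summarised by how codes co-occur at displacement $d$ along the
four canonical directions $\theta \in \{0^\circ,45^\circ,90^\circ,135^\circ\}$
(the standard grey-level co-occurrence convention, $y$ up). Within a centre
region that excludes a 12-px border, every centre $p$ contributes the ordered
pair $(c(p),\,c(p+a_\theta))$ **and** the pair $(c(p-a_\theta),\,c(p))$ for
each direction — i.e. both displacement senses, folded onto the four
canonical directions. Each centre therefore contributes exactly 8 counts and
the histogram total is $8\,|R|$ for a centre region $R$.

This symmetric counting is deliberate. If pairs are counted only with their
*tail* in the region (4 counts per centre), a 90-degree rotation maps two of
the four directions onto the *negatives* of canonical directions; re-basing
the reversed pair moves its tail outside the region on a boundary strip of
width $d$, and exact rotation invariance is lost. Counting each oriented
pair once per endpoint inside the region restores a pair-by-pair bijection
under rotation, so invariance becomes *exact*, not approximate — at the cost
of the conservation constant being 8 rather than 4 per centre. The brute
force oracle in the test suite implements the same convention independently
and agrees cell-for-cell.

## Rotation-orbit pooling

Rotating the image by 90 degrees acts on a raw cell $(\theta, A, B)$ by
rotating both codes (a cyclic bit shift), advancing $\theta$ by 90 degrees,
and swapping $A$ and $B$ when the direction wraps past 180 degrees (the pair
reverses). Pooling the 1024 raw cells over the orbits of this order-4 action
gives **272 invariant bins** — confirmed both by enumeration and by the
Burnside count $(1024 + 0 + 64 + 0)/4$. Note that $\theta$ only alternates
within $\{0^\circ, 90^\circ\}$ or within $\{45^\circ, 135^\circ\}$: a
0-degree pair can never rotate onto a 45-degree pair, so e.g. the all-ties
cell $(15,15,0^\circ)$ has an orbit of size 2 and a constant image occupies
exactly two invariant bins (half the mass each) per scale.

## Multi-scale assembly

The descriptor runs at three scales $(r,d) \in \{(1,2),(2,4),(4,8)\}$. The
displacement is fixed at $d = 2r$ — the radii are part of the method's
definition but the interval is a free choice, recorded in every run
manifest. All three scales share a single centre region (margin 12 px, the
maximum $r+d$), so every scale scans the same centres and the 90/180/270-
degree invariance of the concatenated vector is exact on square images
(asserted as equality in the tests, including after edge enhancement). Each
272-bin block is L1-normalised into a distribution — so image size cancels —
and the blocks are concatenated without inter-block weighting: a feature
vector of $3 \times 272 = 816$ values. Images must exceed 24 px on both
sides so the centre region is non-empty.

Invariance under *arbitrary* rotation angles is approximate only: the "+"
sampling pattern is anisotropic, and bilinear interpolation genuinely
smooths fine texture (iid pixel noise most of all — a real texture change,
not a descriptor artefact). The property test measures a 30-degree rotation
of a large, noise-free structured field (220 px, centre-cropped to 143 px,
where the histograms have converged) and bounds the per-block L1 distance by
0.15; small or noise-dominated fields do not meet that bound and should not
be expected to.

# Classifiers

Two learners sit behind one interface, because the method family this
pipeline belongs to has used both and the choice is genuinely open:

* **`svm_ecoc`** (default): one binary RBF-SVM per class against the rest —
  the one-vs-all coding of an error-correcting output code scheme. Features
  are standardised per dimension (training statistics only, stored in the
  model). When the `C` x `gamma` grid has more than one point, each scorer
  tunes by maximising mean *balanced* accuracy over an inner stratified
  10-fold cross-validation (balanced, because one-vs-all problems are
  heavily imbalanced). The documented default grid is
  $C \in \{0.1, 1, 10, 100\}$, $\gamma \in 10^{\{-2..2\}}/816$; a single
  grid point skips tuning entirely. The package's own synthetic studies use
  the fixed point $C = 10$, $\gamma = 1/816$ ($1/\dim$, the standard RBF
  default), which is well inside the regime where the default-contrast
  classes separate — full grid tuning on 816-dimensional features is
  reserved for smaller problems.
* **`adaboost_trees`**: multi-class AdaBoost (SAMME) over depth-limited
  `rpart` trees, default 100 cycles, vote weight
  $\alpha = \log\frac{1-\varepsilon}{\varepsilon} + \log(K-1)$, sample
  weights renormalised each round. A chance-level weak learner receives zero
  vote and stops the loop; surrogate splits are disabled since descriptor
  features are never missing.

Prediction is the argmax of the four one-vs-all scores; exact ties break
towards the earlier class in the order I, II, III, IV. The scores are kept
for ROC construction.

## Evaluation protocol

The dataset is split into stratified 70/30 train/test partitions,
independently **10 times** (per class, round-half-up of $0.7 \times$ count
to train, remainder to test). Held-out predictions are pooled across
repeats into one confusion matrix and one ROC per class; per-repeat
accuracies are also reported with mean and SD, since the pooled-versus-
averaged aggregation choice is a real degree of freedom and reporting both
lets either convention be read off. A final model is trained on the full
dataset after evaluation. Everything is driven by one integer seed.

Two protocol statements often conflated are kept in distinct roles here:
the *outer* protocol is Monte-Carlo 70/30 splitting (10 repeats); *inner*
10-fold cross-validation is used only for SVM hyperparameter tuning.

## Class imbalance

Routine screening data are dominated by negatives (the package's
`clinical_proportions()` profile: 10.55 / 87.02 / 0.50 / 1.93 %). The
under-sampling variant removes randomly chosen negative rows without
replacement until the negative count equals the positive count, leaving
classes I, III, IV untouched and preserving row order — nothing else is
rebalanced, matching the narrow definition of the procedure this
implements.

# Metrics

Accuracy is trace/total and error its complement (their sum is exactly 1 by
construction). Sensitivity, specificity, precision and F1 are computed on
the one-vs-rest reduction of every class; because a single headline number
for a 4-class task requires choosing the binary reduction, the report
carries the full per-class table plus macro averages, with a designated
`positive_class` (default I) supplying the headline fields. Cohen's kappa
is $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the row/column marginals. AUC
uses the rank (Mann-Whitney) formulation with ties counted one half, which
equals the trapezoidal area under the empirical ROC (asserted against an
independent implementation in the tests). Ratios with zero denominators are
reported as `NA` and flagged in `$undefined`, never silently as 0 — a
single-class truth vector, for instance, has $p_e = 1$ and undefined kappa.
An optional flag drops samples *predicted* equivocal (class IV) from the
accuracy denominator, for the reading convention in which inconclusive
calls are not counted; it is off by default and recorded in the report.

# The synthetic generator

Clinical EmA image sets are private, so the pipeline is exercised on a
seeded generator that renders the four phenotypes through one parametric
template (per-class parameters only — at `separability = 0` every class
collapses onto the across-class mean parameter set and the problem is
chance-level by construction):

| class | morphology | defaults |
|---|---|---|
| I | 4 elliptical ring outlines + 8 fibers/1000 px², coarse mottle | background 0.35, ring 0.55, noise 0.05 |
| II | fine-grained speckle only | background 0.12, noise 0.05 |
| III | near-flat, near-dark | background 0.03, noise 0.015 |
| IV | class-I morphology, low contrast | background 0.18, ring 0.18, fibers 5/1000 px² |

Rings are Gaussian-profile elliptical outlines (random centre, axes
size/10–size/5, orientation); fibers are short (4–10 px) oriented segments
splatted with a narrow Gaussian; the mottle field is smoothed white noise
with class-specific amplitude and correlation length (coarse for
Wharton's-jelly-like background, fine for negative speckle). The negative
and deficient classes deliberately differ in *texture* (speckle grain
versus near-flat), not just brightness, because LBP codes compare intensity
*signs* and are insensitive to overall level. Equivocal is modelled as
low-contrast positive, matching its clinical meaning of weak staining,
which makes I-vs-IV a contrast-to-noise discrimination. Defaults were fixed
once as a plausible stylisation of the four phenotypes; `separability`
interpolates every parameter linearly toward the shared mean.

What the generator does **not** emulate: optics (PSF, vignetting, focus),
JPEG artefacts, the continuum of real staining intensities, inter-slide
illumination drift, or any biological variation beyond the four texture
cues. Passing the synthetic study therefore demonstrates that the
*pipeline* — descriptor, learners, protocol, metrics — recovers texture
classes it was designed to see; it says nothing about clinical performance,
which would require real images. The synthetic task at default contrast is,
by design, easy (held-out accuracy is typically 1.0); its value is as an
end-to-end correctness check, with the `separability = 0` control
confirming the pipeline finds nothing when there is nothing to find.

Fractional per-class counts from a proportions profile are apportioned by
the largest-remainder method so totals are exact (e.g. the screening
profile at $n = 200$ gives counts 21 / 174 / 1 / 4).

# Problem sizes and numerical choices

The packaged studies use 64 px images and 100 images per class (the
acceptance script) — at margin 12 a 64-px image has a $40 \times 40$ centre
region, ample for the histograms — and 10 split repeats with the fixed SVM
point above. The Gaussian blur kernel is truncated at $4\sigma$; per-scale
histograms are normalised only when the region is non-empty; degenerate
inputs (single-class training sets, one-class truth for AUC, images below
25 px) raise typed errors rather than returning misleading numbers.
Stratified splitting requires at least 2 samples per class and guarantees
both sides of every class non-empty. All RNG flows through explicit seeds;
seeded helpers restore the caller's RNG state.

# Known limitations

* The descriptor's arbitrary-angle invariance is approximate and
  texture-dependent (see above); only multiples of 90 degrees are exact.
* One-vs-all SVM decision values are not calibrated probabilities; they are
  used only monotonically (argmax, ROC), and cross-class score comparisons
  inherit the usual one-vs-all caveat.
* The synthetic classes are far cleaner than clinical material; reported
  synthetic accuracies are upper bounds of a sanity check, not performance
  claims.
* Under-sampling discards data; it is the only rebalancing offered (no
  cost-sensitive weighting or synthetic oversampling).
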