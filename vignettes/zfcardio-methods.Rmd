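---
title: "Quantifying cardiovascular phenotypes in zebrafish larvae: models and methods"
author: "zfcardio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiovascular phenotypes in zebrafish larvae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfcardio)
```

## Why this package exists

Zebrafish larvae around 5 days post-fertilization are a standard model
for human cardiovascular disease: the beating heart, circulating
erythrocytes and cerebral vasculature are all optically accessible.
Phenotyping screens of mutant lines — for instance gain-of-function
K~ATP~-channel variants modelling Cantú syndrome, which present with
enlarged hypercontractile ventricles, elevated cardiac output, reduced
venous flow velocity and dilated cerebral vessels — rest on a handful of
measurements taken from calibrated microscopy: ventricular volumes from
high-speed brightfield video, erythrocyte velocities from frame-by-frame
tracking, pericardial area, and 3D vessel volume from confocal stacks.
In practice these measurements are made interactively (ImageJ outlines,
manual cell clicking, Imaris surfaces), which is slow and hard to audit.

`zfcardio` re-implements that measurement chain as tested, scriptable
code, and pairs it with synthetic image generators whose ground truth is
known *exactly*, so that every stage — segmentation, ellipse fitting,
beat detection, tracking, volumetry, statistics — can be validated end
to end without animal data.

## The cardiac model

The ventricle in a single optical section is treated as an ellipse with
long axis $a$ and short axis $b$. Volumes follow the prolate-spheroid
model used throughout the zebrafish literature:

$$V = \tfrac{4}{3}\,\pi\,\left(\tfrac{b}{2}\right)^2 \tfrac{a}{2},$$

i.e. the short axis is taken as both transverse diameters. From the
per-beat end-diastolic and end-systolic volumes (EDV, ESV), averaged
over the first three complete beats ("in triplicate"):

* stroke volume $SV = \overline{EDV_i - ESV_i}$,
* cardiac output $CO = HR \times SV$, reported in nL/min
  ($1\,\text{nL} = 10^6\,\mu m^3$),
* shortening fraction $SF = (a_d - a_s)/a_d \times 100$ from the fitted
  long axes,
* ejection fraction $EF = SV/EDV \times 100$ (the averaged $SV$ and
  $EDV$, not the mean of per-beat ratios — the conventional formula uses
  the already-averaged quantities),
* fractional area change $FAC = (A_d - A_s)/A_d \times 100$.

The heart rate is measured the way it is done at the microscope: the
time interval spanning three heartbeats, $HR = 3 \times 60/\Delta t$,
with $\Delta t$ taken from the first diastole to the fourth. The
phrasing "interval between three heartbeats" is ambiguous between two
and three periods; we fix it at three periods (diastole $i$ to $i+3$).

All lengths are micrometres, areas $\mu m^2$, volumes $\mu m^3$
internally; reports also carry volumes in nL. Calibration (fps, µm/px,
z-step) is always user-supplied and never inferred from pixels — a
missing calibration is an error, never a silent default of 1.

### Segmentation and the equal-moments ellipse

`segment_ventricle()` automates the manual perimeter outline: a global
threshold (Otsu's histogram criterion by default, computed per frame),
hole filling, and selection of the largest connected component.
"Fit-to-ellipse" is interpreted as the *equal-moments* (moments-
equivalence) ellipse: the ellipse sharing the region's centroid and
second central moments. With eigenvalues $\lambda_1 \ge \lambda_2$ of
the pixel-coordinate covariance, the axes are $a = 4\sqrt{\lambda_1}$
and $b = 4\sqrt{\lambda_2}$ (calibrated), and the orientation is the
leading eigenvector direction in $[0, \pi)$, reported as 0 for
rotationally symmetric regions (relative eigenvalue gap below $10^{-3}$).
This is the standard definition behind the behaviour of the classical
ImageJ measurement and has the useful property that $\pi a b/4$ equals
the mask area in the continuum limit — the package tests enforce
agreement within 2 %.

### Beat detection

The per-frame area trace is smoothed with a centred moving average of
`round(fps/10)` frames — wide enough to suppress rasterisation jitter,
narrow enough to preserve 2–4 Hz cardiac dynamics. The dominant period
comes from the first autocorrelation peak; diastoles are local maxima
separated by at least 0.4 dominant periods, systoles are the minima
between consecutive diastoles (which enforces strict alternation). A
recording conventionally starts at end-diastole, so a falling first
sample counts as a peak; a rising *last* sample does not, because its
true peak lies beyond the recording. At least three complete
diastole–systole–diastole beats are required; a flat trace (relative
amplitude below $10^{-3}$) is reported as "no contraction" with zero
stroke volume and `NA` heart rate rather than an arbitrary beat set.
A series with no dominant autocorrelation peak (maximum below 0.2) is
likewise rejected — noise alone cannot fake a heartbeat.

## Blood-flow velocimetry

Erythrocytes are detected per frame as dark blobs. The default
threshold is the *midpoint* between the frame median (the background
level, since cells cover a tiny fraction of the field) and the frame
maximum after polarity normalisation; Otsu's criterion is deliberately
not the default here because it assumes a sizeable foreground class and
over-segments frames that are almost entirely background. Blobs outside
the admissible radius range, and blobs touching the field border (their
centroids are biased toward the visible fragment), are discarded;
centroids are intensity-weighted and sub-pixel.

Linking is greedy mutual-nearest-neighbour between consecutive frames:
a link forms only when track and detection are each other's nearest
neighbour within `max_disp`, smaller displacements linked first. This
is deterministic and adequate for the few, sparse cells the assay uses;
it is *not* a global assignment and will fragment tracks when the
per-frame displacement approaches the inter-cell spacing — the package
keeps that failure mode visible (fragmented tracks) rather than
guessing.

Two scoring modes mirror the two vessels:

* **vein** — venous flow is steady, so each of the three longest tracks
  is scored over its first ten frames (mean frame-to-frame displacement
  × pixel size × fps) and the three velocities averaged;
* **aorta** — aortic flow is pulsatile, so each cell is averaged over
  its *entire* track (which must span at least 80 % of the recording);
  over whole pulse periods the sinusoidal modulation integrates away.
  The classical description ("analysed over the whole imaged area") is
  spatial, but its stated purpose is temporal averaging of pulsatile
  flow; we implement the temporal reading.

## Vessel volumetry

A confocal stack of the ring-shaped cerebral arterial circle (the
BCA/PCS loop, the zebrafish analogue of the circle of Willis) is
thresholded globally (pooled-histogram Otsu by default — acquisitions
use identical imaging conditions across samples), labelled with
26-connectivity in 3D, and reduced to the component containing a seed
voxel (or the largest component). This mirrors "eliminating interfering
vessels" before measuring. Volume is the voxel count times the full
anisotropic voxel volume $d_z d_y d_x$. 26-connectivity is chosen to
tolerate thin diagonal vessel runs; interactive surface-smoothing
parameters of commercial tools are unreported anywhere, so thresholding
plus voxel counting is the transparent substitute — absolute volumes
are therefore comparable only within this pipeline, which is exactly
how the group comparisons use them.

## Statistics

The comparison layer reproduces the conventional analysis: values are
summarised as mean ± s.d. (n−1 denominator); normality is checked with
the D'Agostino–Pearson omnibus test ($K^2 = Z_{skew}^2 + Z_{kurt}^2$,
$\chi^2_2$ under normality, undefined below $n=8$); and the two-group
test is a two-tailed unpaired *pooled-variance* Student's t-test when
both groups pass normality at $\alpha = 0.05$ (groups too small to test
are treated as passing), otherwise a two-tailed Mann–Whitney U test.
The published convention names both tests without a per-panel rule;
the normality-gated policy reconciles them, and both tests are always
computed and reported so the trail is auditable, and either can be
forced. The Mann–Whitney p-value is exact (full enumeration of the U
distribution via the standard counting recursion) when
$n_1 n_2 \le 400$ and there are no ties, otherwise the normal
approximation with tie and continuity corrections. Zero variance in
both groups with equal means yields $p = 1$ by convention, flagged.
Screening efficiencies are percentages rounded half-up to one decimal,
matching how such counts are conventionally printed (20/28 → 71.4 %).
These statistics are implemented from their defining formulas; the test
suite cross-checks them against independent implementations
(`t.test`, `wilcox.test`, `dwilcox`, a brute-force `combn` enumeration,
and values frozen from scipy).

## The synthetic generators

Each generator renders what the corresponding assay images, with every
derived ground-truth quantity recomputed through the *same formula
functions* the measurement chain uses:

* **Heart** (`simulate_heart_video`): a filled ellipse whose axes follow
  a raised cosine between diastolic and systolic extremes,
  $a(t) = a_s + (a_d - a_s)(1 + \cos 2\pi f t)/2$, $f = HR/60$, frame 1
  exactly at end-diastole. The classical description fixes only the two
  extremes; the raised cosine is the smoothest periodic interpolation
  that attains them exactly. Defaults mirror a real acquisition: 150
  fps for 10 s (≈30 cycles at 180 bpm), diastolic axes 120 × 80 µm,
  systolic 100 × 60 µm.
* **Flow** (`simulate_flow_video`): dark discs on a bright background
  advected along +x at constant velocity (vein) or with
  $v(t) = v(1 + m \sin 2\pi f_p t)$, $m < 1$ (aorta); cells leaving the
  field re-enter at $x = 0$. No vessel walls are drawn — velocimetry
  needs only moving cells. Cells travel in distinct lanes separated by
  more than a cell diameter, the regime the assay itself requires
  (three individually identifiable erythrocytes).
* **Vessels** (`simulate_vessel_stack`): a torus (centreline radius
  $R$, tube radius $r$; true volume $2\pi^2 R r^2$) with an optional
  disconnected straight tube as the interfering vessel.

Rasterisation uses the pixel/voxel-centre rule (a pixel is foreground
iff its centre is inside the shape) — deterministic, and mask area
approaches $\pi a b/4$ with resolution. Noise is additive Gaussian,
rounded and clipped to the 8-bit range; with zero noise the generator
masks are exactly recoverable by midpoint thresholding, which the tests
assert. Identical seed and parameters give bit-identical output, and a
generator's RNG use is local (the session RNG stream is untouched).

What the generators deliberately do **not** emulate: optical blur and
anti-aliased edges, intensity gradients and vignetting, out-of-plane
motion of the heart, cell shape change and overlap, vessel wall signal,
and photobleaching. Passing the validation suite therefore shows the
*computational* chain is correct and self-consistent at realistic noise
levels — it does not certify performance on real microscopy, where
segmentation quality is the binding constraint.

## Cohorts and reproducibility

`run_cohort()` wires generation → measurement → statistics into the
wild-type-vs-mutant design of a phenotyping screen: each group carries
one parameter set, individual $i$ of the cohort is simulated with seed
`base_seed + i`, every applicable metric is measured with the standard
chain, and each metric is compared between the reference group and
every other group. Re-running a spec reproduces every number
bit-exactly. Failed individuals are recorded and skipped; a group
falling below three usable individuals aborts the cohort. Default
cohort sizes in the examples (15 per group) sit in the 7–21 range
typical of such screens.

## Problem sizes used in the validation suite

The acceptance checks trade recording length against replication so the
whole suite runs on a laptop-class machine; these are package choices,
stated here once:

* cardiac parameter recovery: 10 hearts at 150 fps × 2.5 s, 160×160 px
  at 1 µm/px, spanning HR 120–240 bpm and SF 5–30 %;
* cohort experiments: 100 replicate cohorts of 2 × 15 individuals at
  50 fps × 2 s, 72×72 px at 2 µm/px (≥5 beats per recording — ample for
  triplicate measurement);
* Monte-Carlo spheroid integration: $10^7$ samples per axis pair;
* type-I calibration: 2000 null comparisons of $n = 15$ vs $n = 15$.

The two-second cohort recordings keep ≈24 frames per beat at 150 bpm,
which quantises the three-beat heart-rate estimate to about ±2 bpm —
group comparisons are unaffected since both groups share the design.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on integer histograms; a uniform frame
  has no separating threshold and yields a "no object" error.
* The orientation tie-break for circular regions is $\theta = 0$.
* Ellipse/mask degeneracies (fewer than 5 pixels, collinear pixels)
  raise classed errors rather than returning NaN axes.
* ESV exceeding EDV after measurement is an inconsistency error — it
  indicates segmentation failure, not physiology.
* Crossing particles within `max_disp` are resolved by smallest
  displacement; the tie-break is deterministic.
* Reports round-trip bit-exactly through CSV (17 significant digits)
  with a JSON sidecar for per-beat/per-track detail.

## Known limitations

* Single-plane ellipsoid volumetry is a model, not a measurement of
  volume; its accuracy on real hearts depends on the chosen optical
  section. The package validates recovery of the model's parameters,
  not the model itself.
* The linker is frame-to-frame greedy; dense or fast-crossing cells
  need a global-assignment tracker, which is out of scope.
* Pericardial landmarks are human-supplied polygon coordinates;
  automated landmark detection is out of scope.
* Absolute vessel volumes depend on the thresholding convention and are
  comparable only within this pipeline.
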