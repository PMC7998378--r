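---
title: "hypoxiq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hypoxiq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiq)
```

## What this package computes

Hypoxic tumor cells are radioresistant for two distinct reasons: the oxygen
effect (fewer DNA double-strand breaks are chemically fixed when oxygen is
absent at the moment of irradiation) and, as recent work on hypoxia-induced
quiescence shows, a cell-cycle effect — hypoxia drives cells into a
G0/G1-arrested state that remains radioprotective for some time after
reoxygenation. Testing that hypothesis requires a battery of quantitative
assays, and `hypoxiq` implements their analysis machinery end to end:

* **clonogenic**: colony-forming-assay statistics — plating efficiency,
  surviving fractions, linear-quadratic (LQ) fitting, extra-sum-of-squares
  F-tests between survival curves, iso-effect doses;
* **foci**: per-nucleus counting of γH2AX/53BP1 damage foci in two-channel
  microscopy images, with the group-comparison statistics;
* **fucci**: FUCCI (red = Cdt1/G1, green = Geminin/S-G2-M) state
  classification, per-cell phase-duration tracing, non-cycling scoring,
  Kruskal–Wallis and Fisher-exact statistics;
* **cdk2**: CDK2-activity reporter quantification (cytoplasm/nucleus median
  ratio; quiescent fraction below a 0.55 ratio);
* **section2d**: zonal analysis of IHC-stained spheroid cross-sections
  (H-AEC color deconvolution, k-means hypoxia masks, 10 µm distance zones);
* **spheroid3d**: 3D FUCCI spheroid stacks — per-slice segmentation, sphere
  fitting, exact 2D→3D shortest-distance correction, radial green/red
  histograms;
* **synthetic**: generators for every one of those inputs with known ground
  truth, making all of the above testable in closed loop;
* **pipeline_cli**: a YAML-configured, seed-deterministic orchestration
  layer and `hypoxiq` CLI.

## Models and procedures

### Linear-quadratic survival and curve comparison

Surviving fraction after dose $D$ follows
$\mathrm{SF}(D) = e^{-\alpha D - \beta D^2}$. Fitting is ordinary least
squares in log-SF space, where the model is linear in $(\alpha, \beta)$,
under the physical constraint $\alpha, \beta \ge 0$ (active-set over the
two parameters; an active constraint is flagged). Each well contributes one
point so that degrees of freedom reflect true replication. Wells with zero
colonies at positive dose are excluded from the log fit with a warning.

Two curves are compared with the extra-sum-of-squares F-test:
$F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/2}{\mathrm{RSS}_2/(n_a+n_b-4)}$,
where $\mathrm{RSS}_1$ comes from one pooled fit and $\mathrm{RSS}_2$ from
separate fits. The test is exact under its own assumption — independent
homoscedastic Gaussian errors in log-SF — and our acceptance battery
confirms nominal type-I control (rejection rate ≈ 0.05) in exactly that
regime. A caveat worth knowing: when survival points are produced by the
full plating pipeline, normalization by a *shared estimated* plating
efficiency correlates all points of a condition and Poisson counting noise
is heteroscedastic across doses; both inflate the type-I error of the
naive F-test. The package implements the standard test as practiced; the
calibration property is stated, and tested, under the model's own error
assumptions.

The iso-effect dose inverts the LQ model in closed form as the positive
root of $\beta D^2 + \alpha D + \ln \mathrm{SF} = 0$.

### Foci counting

Nuclei are segmented classically: Gaussian smoothing (1 µm), Otsu
threshold, hole filling, distance-transform watershed with markers at
distance maxima (minimum separation 6 µm), minimum area 30 µm². The foci
detector is the standard "foci macro" idiom: white top-hat with a 1.5 µm
disk, a per-nucleus robust threshold (median + 5·MAD of the enhanced
signal inside the nucleus), local maxima, and merging of maxima closer
than one focus diameter (1.5 µm). Because every ingredient is relative
(medians, MADs, maxima), counts are invariant under affine intensity
rescaling — a tested property. The original macro's internals are not
published; these defaults are design decisions, exposed as parameters.

### FUCCI gating and tracing

Gating follows the standard quadrant logic: red-high/green-low = G1,
green-high/red-low = G2(/M), double-high = S, double-low = early G1, with
values exactly at a gate counting as "low" (a declared tie rule). Gates are
calibrated automatically by 2-class Otsu on log intensities — deterministic
and scale-equivariant — because published gates are drawn by eye on density
plots; unimodal channels fall back to median × 2 with a warning.

Per-frame states are smoothed with a 3-frame majority filter (one-frame
states are unphysiological at 30-min sampling), runs are timed, and cells
are scored by two non-cycling rules: residence in a single phase beyond
24 h (stall), or a green→red reversal without an intervening mitosis
(slip). Two deliberate choices:

* **Rule precedence.** Slip is checked before stall. A slipped cell that
  then sits red for the rest of a 120 h movie would otherwise be
  mislabelled a stall; the biology (cell-cycle exit) and the reversal event
  itself are what distinguish slip. This deviates from a literal
  first-rule-wins reading but is required for the subtype labels to mean
  what they say.
* **Movie end.** Whether a cell mid-phase at the last frame is non-cycling
  or merely censored is genuinely ambiguous; `movie_end_rule` exposes both
  behaviors. The default (`"threshold"`) stalls the cell only if its
  current residence already exceeds 24 h, else censors. We use a per-trace
  threshold rather than a cohort median so that a single trace's result
  never depends on which batch it was processed in.

Kruskal–Wallis (tie-corrected, χ² approximation) compares duration
distributions; the cycling/non-cycling association uses the exact
two-sided hypergeometric test (sum of all tables with probability not
exceeding the observed), with a Haldane-corrected sample odds ratio when a
cell is zero. The Fisher p-value is verified against full enumeration for
every 2×2 table with N ≤ 40.

### CDK2 reporter

The DHB-Venus reporter leaves the nucleus as CDK2 activity rises, so the
cytoplasm/nucleus median-intensity ratio tracks activity and ratios below
0.55 (strict inequality — "lower than") mark quiescence. The pipeline:
rolling-ball background subtraction at 50 µm, nuclear segmentation, a
1.5 µm cytoplasmic band per nucleus with crowding resolved by exact
nearest-nucleus assignment (ties to the lower label), then the ratio of
medians. "Rolling ball" is realized as grayscale opening with a disk of
the stated physical radius; at these radii the difference from the
paraboloid variant is negligible, and the disk makes results
bit-reproducible. For radii above 32 px the background is estimated on a
4× block-minimum-reduced image and re-expanded (the standard large-radius
shortcut), clipped to remain a lower envelope.

### Cross-section zonal analysis

RGB images are converted to optical density ($\mathrm{OD} =
-\log((I+1)/256)$) and unmixed against unit stain vectors for hematoxylin
and AEC (Ruifrok–Johnston convention; third vector = normalized cross
product). The synthetic generator composes images with the same matrix, so
unmix∘mix is exact to machine precision on noiseless data — a tested
round trip. The section rim is outlined from summed OD with a two-pass
threshold: a tissue floor (min(Otsu, 0.15 OD)) finds tissue at all, then
half the median tissue OD trims the blur halo; on strongly stained
sections the OD histogram is trimodal and a plain Otsu would latch onto
the stain contrast instead of the tissue edge.

The pimonidazole (hypoxia) mask thresholds AEC OD inside the section by
2-means. For one-dimensional data the k-means optimum is a contiguous
split of the sorted values, which we compute exactly — a deterministic,
seedless improvement over Lloyd iterations with restarts. Because a
2-means split always exists, the positive class is accepted only when the
cluster means differ by at least 0.1 OD (chromogen deposits are far above
this); marker-free sections therefore yield empty masks rather than noise
masks. BrdU positivity uses the same rule, by symmetry — the BrdU
threshold is not stated in the source protocol.

Distance zones are `floor(depth/10 µm)` over the Euclidean distance
transform measured inward from the rim (geodesic and Euclidean distances
agree on near-convex sections). Zone pixel counts partition the section
exactly; positive-pixel counts are conserved across zones — both tested
invariants. Alignment of the BrdU- and pimonidazole-stained serial
sections automates a manual step by phase correlation of the two section
masks (whole-pixel translation; a sub-threshold correlation peak falls
back to the identity with a warning).

### 3D spheroid analysis

Per slice, both channels get a 100 µm rolling-ball subtraction; the green
channel is rescaled so its mean over green-positive voxels (global Otsu)
matches the red positive mean; channels are then summed. Slices are
outlined by median filter (5 µm) → Gaussian (5 µm) → Huang threshold →
largest component → fill. Nuclei are segmented per 2D slice (10 µm
z-steps make true 3D segmentation impossible), with watershed markers
taken from smoothed-intensity maxima — in packed tissue the thresholded
mask is one merged blob, so distance-transform markers would collapse it
to a single object.

The sphere is fitted from per-slice *areas*: the equivalent radius
$r_i = \sqrt{A_i/\pi}$ is robust to ragged outlines, and
$r_i^2 + z_i^2 = (R^2 - z_c^2) + 2 z_c z_i$ is linear in its two
unknowns, making the fit exact on noiseless circles. The shortest distance
from a nucleus at in-plane rim distance $d_2$ in the slice at height $z$
to the spherical surface is
$d_3 = R - \sqrt{(r_z - d_2)^2 + (z - z_c)^2}$ — the unique
shortest-distance solution under the spherical assumption, verified
against a brute-force nearest-surface-point search to < 0.1 µm. Nuclei
that the fitted sphere does not cover (segmentation noise near the caps)
are clamped to distance 0 and flagged. Cells are green iff
$g/(g+r) > 0.225$ (strict), and 10 µm radial bins carry the green
fraction with red = 1 − green.

## The synthetic world

The generators emulate the *structure* each analysis assumes, not the
appearance of micrographs. Stated-world defaults: colony counts are
Poisson around $250 \times \mathrm{PE} \times \mathrm{SF}(D)$ with 6
technical replicates of 250 seeded cells; FUCCI phases default to
2/8/7/3 h (early G1/G1/S/G2) at 0.5 h frames over a 120 h movie with 10%
log-normal intensity noise; stall cells halt in a uniformly chosen phase,
slip cells revert green→red at a uniform random G2 frame. Geometry is
parameterized in µm at a default 0.65 µm/px (typical 10× camera sampling;
no acquisition pixel size is stated in the source protocols). Where the
stated world is silent we declared once: nuclei are 10 µm-radius disks
(7 µm in the reporter images), foci are Gaussian puncta of 1.5 µm
diameter with amplitude far above the 2-unit readout noise, sections carry
0.5 hematoxylin OD with 0.8–0.9 AEC OD in positive areas, and spheroid
nuclei sit on a jittered 11 µm grid on each imaged plane so that slice
segmentation remains well-posed.

What a green closed loop establishes: that the analysis recovers planted
truth under the stated noise and geometry. What it does not establish:
robustness to autofocus failure, uneven illumination, stain variability
between laboratories, segmentation of overlapping or apoptotic nuclei, or
tracking errors in trace linkage — real-data failure modes the generators
deliberately do not model.

## Numerical choices and budgets

* Exact Euclidean distance transforms (Felzenszwalb–Huttenlocher) and
  van Herk sliding extremes make morphology exact, not approximate; the
  only approximation anywhere is the documented large-radius rolling-ball
  shortcut.
* All randomness flows from one seed through a fixed per-stage derivation,
  so every generator and the whole CLI are byte-deterministic (tested by
  hashing outputs).
* Heavy closed-loop tests run at 1.3 µm/px (2× binning of the default)
  purely for CPU budget; the criteria they check are stated in µm and are
  insensitive to this choice.
* Plateaus in distance/intensity relief are broken by an additive index
  ramp ~9 orders of magnitude below the data scale, making marker
  selection deterministic without perturbing values.

## Known limitations

* The F-test inherits the usual fragility of extra-sum-of-squares testing
  under heteroscedastic, group-correlated noise (see above).
* Section alignment is whole-pixel translation only; rotation is out of
  scope and flagged via the correlation peak.
* Foci are counted in 2D maximum projections; 3D foci and γH2AX/53BP1
  colocalization are out of scope.
* Trace linkage across frames is assumed done upstream; the tracer
  consumes linked traces.
* LQ parameter tables of the original study are not printed in its text,
  so no numeric cross-check against published α/β values is possible; the
  acceptance battery is property-based on synthetic data instead.
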