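---
title: "Simulating TMS functional network targeting: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TMS functional network targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmstarget)
```

# The question and the model

Network-guided TMS asks which resting-state network a given coil placement
actually stimulates. The answer combines two physical/statistical models:
the induced electric field on the cortical sheet, and the seed-based
functional connectivity of the stimulated region. `tmstarget` implements
the standard targeting pipeline — field-thresholded weighted seeds, shared
covariate partial correlation, top-percentile sparsification, Yeo-7
overlap assignment, zone/orientation aggregation, EFSI — on synthetic
surfaces where ground truth is known, and on user-supplied data in the
same interchange formats.

## Electric field: free-space primary field of a figure-8 coil

The field engine computes the primary field only: each circular loop
(radius 35 mm, i.e. a 70 mm figure-8; opposite winding sense) is
discretized into `segments` straight elements (default 64), and

$$\mathbf A(\mathbf r) = \frac{\mu_0 I}{4\pi}
  \sum_k \frac{\Delta \mathbf l_k}{|\mathbf r - \mathbf m_k|},
  \qquad |\mathbf E| = \left|\frac{d\mathbf A}{dt}\right|,$$

with segment midpoints $\mathbf m_k$. A full volume-conductor FEM with
tissue conductivities is deliberately **not** implemented: it needs
segmented head models that are out of scope at desk scale, and the
homogeneous (primary-field) approximation already reproduces the
qualitative behaviour that drives the analysis — field strength decays
with coil-to-cortex distance, so gyral crowns sitting closer to the coil
receive systematically stronger fields than sulcal floors. The package
documents this substitution prominently; absolute V/m values should not
be interpreted quantitatively. The discretization error of the segment
sum is bounded by an elliptic-integral closed form for a single loop
(arithmetic-geometric-mean evaluation of $K$ and $E$), which the test
suite checks to within 1% at 64 segments.

One geometric subtlety: the vector potential of a circular loop is
identically zero *on* its axis by symmetry, so the closed-form comparison
is made at off-axis cylindrical points $(\rho > 0, z)$ where $A_\phi$ is
nontrivial.

The coil plane sits at the species `standoff` above the highest point of
the patch (scalp, skull and CSF collapsed into one distance); the handle
at 0° points along +y ("midline") and rotates in the tangent plane in 15°
steps over a half-circle, since a figure-8 field is symmetric under 180°
rotation.

## Synthetic surfaces

Two species profiles fix the stated world:

| parameter | human-like | macaque-like | why |
|---|---|---|---|
| patch extent | 120 × 120 mm | 64 × 64 mm | prefrontal cortical sheet is up to ~1.9-fold larger in humans |
| grid spacing | 10 mm | 5 mm | the stimulation-grid conventions for each species |
| fold layout | multi-gyral (cosine folds) | single dominant gyrus (Ricker profile) | human prefrontal cortex is highly gyrified; macaque has one prominent gyrus |
| fold amplitude / wavelength | 10 / 30 mm | 5 / 24 mm | order-of-magnitude human gyral relief and spacing; shallower macaque folds |
| coil standoff | 15 mm | 6 mm | typical scalp-to-cortex distances |

The Ricker (Mexican-hat) cross-section was chosen for the dominant gyrus
because it is the simplest smooth profile with exactly one crown flanked
by two sulci and no secondary maxima — a property the tests assert on
every cross-fold transect. Fold phases and the crown position get small
seed-controlled jitter so that mesh generation is a pure, non-degenerate
function of (profile, resolution, seed). The default resolution
(0.35 vertices/mm) yields ~1.8k vertices for the human patch and ~0.5k
for the macaque patch: the pipeline math is resolution-agnostic, and
standard 32k surfaces are intentionally not reproduced.

Parcellations are painted as rectangles in fractional patch coordinates.
The human-like default puts the Default network (DN) medially and the
Frontoparietal network (FPN) laterally with a posterior
somatomotor/attention strip; the macaque-like default puts FPN on the
gyral crown, somatomotor posteriorly, and small DN/attention patches.
These layouts are calibration-free geometric stand-ins for the real label
maps — coarse in shape, but they preserve the one property the analysis
is sensitive to: which network underlies each part of the stimulation
grid.

## Synthetic fMRI

Each network $n$ has a latent AR(1) series $g_n(t)$ and every vertex in
$n$ observes $x_v(t) = a_n g_n(t) + \sigma \varepsilon_v(t)$; label-0
vertices get pure noise. The latents are scaled to **unit stationary
variance** (innovation sd $\sqrt{1-\rho^2}$) so that the within-network
population correlation is exactly $a_n^2/(a_n^2+\sigma^2)$ for every
$\rho$ — with unit *innovation* variance that identity would hold only at
$\rho = 0$. Defaults: $a_n = 2$, $\sigma = 1$ (population correlation
0.8, noise sd fixed at one unit), $\rho = 0.3$ (slow, smooth latents on
the scale of a 0.72 s TR), human-like $T = 1200$ at TR 0.72 s (a
15-minute run), macaque-like $T = 1600$ at TR 2.0 s — a desk-scale
emulation of a 53-minute anesthetized run; the macaque TR is an assumed
value, not sourced. Band-pass filtering (0.01–0.1 Hz, DFT zeroing,
DC removed) is available but off by default, since the generator already
produces band-limited-like smooth latents. Preprocessing (motion, nuisance
regression, smoothing) is not simulated: the analysis under test begins
after preprocessing, so the generator directly emits the covariance
structure those steps aim to expose.

## Connectivity and assignment choices

Several points are under-determined by the method's usual description;
the package fixes them explicitly:

* **Seed weight normalization.** "Normalizing the electric field" is read
  as dividing by the within-seed *sum*, making the seed series a convex
  combination — which is what "weighted average" means. Max-normalization
  is available (`seed_normalize = "max"`); it changes only the scale of
  the seed series and hence nothing downstream of the correlation.
* **Intercept.** The covariate regression includes an intercept; residual
  correlation without demeaning is not a correlation.
* **Undefined vertices.** Residual variance below 1e-12 yields `NA`, not
  0, so degenerate vertices cannot compete in top-percentile ranking.
* **Sparsity.** `k = max(1, floor(0.01 · defined))` vertices with the
  highest *signed* r are kept; ties at the cutoff break toward the lower
  vertex index. Absolute-value ranking is a flag (`use_abs`), and Dice
  overlap an alternative metric (`metric = "dice"`), both robustness
  variants rather than the primary definition.
* **Ties in assignment.** Exact overlap ties resolve to the lowest
  network code (so an FPN/DN tie resolves to FPN, code 6 < 7) and are
  flagged rather than hidden.
* **EFSI definition.** The phrase "percentage of nodes within GM greater
  than 50% of the maximum across all simulations" admits two readings.
  The implemented primary definition is *per vertex*: the percentage of
  configurations in which the vertex exceeds half of that configuration's
  maximum (consistent with reporting a region as suprathreshold "in 91%
  of simulations"). The per-configuration complement — percentage of
  vertices above threshold in each map — is returned as the
  `per_map_percent` attribute. The package does not claim to resolve the
  ambiguity; it exposes both.
* **Zones.** `zone = 3·floor(row/2) + floor(col/2) + 1` with row 0
  anterior (max y) and column 0 medial (min x): Z1/Z4/Z7 are the medial
  zone column, Z3/Z6/Z9 lateral. On real data the grid-axis convention
  must be supplied by the user; the synthetic convention is documented,
  not claimed to match any scalp registration.

## Determinism and seeds

One global seed expands into fixed-offset child seeds for the mesh,
parcellation and fMRI stages, so changing the fMRI realisation never
perturbs the geometry. Mesh generation, field evaluation and the full
pipeline are bitwise deterministic under a fixed config + seed; the run
directory includes a JSON provenance record sufficient to reproduce the
run. RNG state is saved and restored around all internal seeding.

## What a green test establishes — and what it does not

The planted-recovery and zone-structure tests establish that the pipeline
correctly recovers *known* network structure through the full chain
(fields → seeds → partial correlation → sparsification → assignment) at
realistic run lengths and SNR, and that the geometry-driven mechanism
(crown concentration of the field, hence FPN dominance on a single-gyrus
patch) emerges from the field model rather than being painted in. They do
**not** establish quantitative agreement with subject-level imaging
results: real cortical geometry, FEM conductivity structure,
between-subject variability, anesthesia effects and real network
topography are all outside the synthetic world, which is why the source
study's headline percentages are explicitly not acceptance targets.

## Known limitations

* Primary-field model only; no secondary (charge accumulation) field, so
  sulcal field enhancement at CSF–GM interfaces is absent by design.
* Euclidean distance stands in for geodesic distance in the planted
  Gaussian field fixture; acceptable on shallow patches only.
* Rectangular-band parcellations cannot represent interdigitated
  networks.
* Anesthesia is representable only as reduced latent amplitudes.
* GIFTI I/O is not provided; interchange is ASCII PLY / TSV / JSON.
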