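---
title: "Detecting hotspots of bipolar-cell input on retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hotspots of bipolar-cell input on retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotter)
```

## The scientific question

ON smooth monostratified retinal ganglion cells (RGCs) have a striking
receptive-field structure: isolated regions of high light sensitivity
("hotspots") separated by insensitive "coolspots". Their dendrites
co-stratify with ON parasol RGCs in the inner plexiform layer (IPL), so
both types can only sample the same co-stratifying bipolar cell types
(DB4, DB5, DB6, giant, ON midget). One anatomical explanation of the
hotspots is that excitatory ribbon-synapse input from bipolar cells is
spatially clustered on the smooth cell while it is homogeneous on
parasols. `hotspotter` implements the complete quantitative chain needed
to test that idea on skeletonized volume-EM reconstructions:

1. density maps of synapse and dendrite positions,
2. Gaussian-mixture clustering of ribbon-synapse coordinates with
   Calinski–Harabasz (CH) model selection and Mahalanobis outlier
   exclusion,
3. convex-hull morphometry and IPL depth profiles,
4. connectivity statistics: amacrine/bipolar proportions, a geometric
   null for runs of consecutive amacrine synapses, per-partner synapse
   loads, Fisher's exact comparisons, and the overlap of one cell's
   synapses with another cell's dendritic field.

Because the original annotations live on a remote EM-volume server, the
package ships a synthetic reconstruction generator whose planted ground
truth makes every stage independently verifiable.

## Data model

A `scene_dataset` holds annotation-disk skeletons (`nodes.csv`: disk
centre in µm, radius, parent link, soma/dendrite/axon tag), a cell table,
a synapse table (`synapses.csv`: pre/post cell, ribbon vs conventional
kind, 3D position, presynaptic type label), and the two IPL boundary
planes (`ipl.json`). Depth is expressed as a percentage: the INL/IPL
boundary is 0 %, the IPL/GCL boundary 100 %. All cluster, density and
hull analyses are planar (x–y): the mapped structures are essentially
monostratified, so the z extent carries stratification information, not
hotspot structure. Ribbon synapses imply a bipolar presynaptic cell and
conventional synapses an amacrine cell; both rules are enforced at
validation. IPL boundaries are modelled as flat planes; warped-surface
support would be an extension of the same schema.

Synapses are attached to skeletons by nearest node in 3D, ties broken
toward the lower node id — the rule every arc-length computation uses.

## The synthetic generator

`generate_skeleton()` grows a dendritic tree from discrete segments
(default 2 µm). Growth is *self-avoiding and space-filling*: a tip whose
azimuthal neighbour is closer than `branch_spacing` steers toward the
open side, and branching is permitted only into gaps wider than twice
that spacing. An outward tropism (`radial_bias`) keeps dendrites growing
away from the soma. Together these rules tile the dendritic field with
approximately uniform cable density, the behaviour real radiate dendritic
fields show, and they remove two artefacts simpler growth models produce
(exponential tip multiplication, azimuthal holes). Two default
configurations encode the study's cell classes:

* `smooth_skeleton_config()`: 8 primary dendrites, 76.5 µm field radius
  (≈153 µm hull diameter), low angular noise (0.08 rad/segment — nearly
  straight, radiate), 4 µm branch spacing, soma radius 7.25 µm,
  stratifying at 63.2 % of a 40 µm IPL;
* `parasol_skeleton_config()`: 28.5 µm field (≈57 µm hull), high angular
  noise (0.35 rad — tortuous), 3.5 µm spacing, soma radius 7.45 µm,
  stratifying at 64.6 %.

`place_synapses()` makes each of `n_synapses` independently amacrine with
probability `amacrine_fraction` (default 0.615, the 1.6:1
amacrine:bipolar ratio) and otherwise a bipolar ribbon synapse. Bipolar
synapses sit on dendrite nodes drawn with probability proportional to a
planted mixture intensity (`planted_hotspots()`: four equal components at
(±38, ±38) µm, SD 8 µm, ≥60 µm apart) or uniformly along the cable for
the homogeneous control. Sampling node positions with
intensity-proportional weights is exactly the rejection-sampling scheme
"propose a node uniformly, accept with probability ∝ intensity", without
the loop. Because synapses must lie on cable, the generator can decouple
dendrite density from synapse clustering — the comparison at the heart of
the analysis. Presynaptic types are multinomial
(smooth default: DB5 0.52, DB4 0.26, giant 0.15, unclassified 0.07);
classified ribbon synapses choose a partner from a spatially coherent
pool of axon-terminal centres with a 12 µm proximity kernel, giving
realistic per-partner synapse loads (≈2 for the sparse smooth cell).

`generate_paired_scene()` combines one smooth cell with parasols placed
inside its field, shares one partner pool across all cells (so
shared-partner analyses are meaningful), and records the planted truth as
a `truth.json` sidecar.

**What the generator does not emulate.** Dendrite diameters are constant;
there is no 3D neurite avoidance, no axons, no correlation between cable
density and planted hotspots (real smooth cells show a partial
correlation); a `branch_spacing` of 4 µm is denser than a real smooth
RGC's cable, a choice made so that cable-constrained sampling realizes the
planted mixture with a centroid bias of ~1–3 µm, well under the 4 µm
recovery tolerance used in testing. Passing the planted-recovery tests
therefore demonstrates correctness of the clustering pipeline on scenes
whose ground truth is faithfully realized — not that hotspot detection is
unbiased on arbitrarily sparse cells (on sparser trees the synapse
centroid of a cluster genuinely moves toward where the cable is, which is
a property of the specimen, not of the estimator).

## Density maps

`density_map()` bins x–y positions on a grid (bounding box padded by one
bin; origin snapped to a bin multiple so translated point sets give
translated maps) and smooths with a second-order difference-penalty
(Whittaker) smoother applied separably along rows and columns with
penalty λ (default 1, "minimum smoothing"). Because a second-difference
penalty annihilates constants, the all-ones vector is an eigenvector of
(I + λDᵀD) with eigenvalue 1 and the smoother conserves total mass
exactly: the grid always sums to the number of points. λ = 0 returns the
raw histogram bit-exactly. The smoother can ring slightly below zero next
to sharp peaks; negative bins are clamped to zero and the map rescaled so
the total still equals the point count (at λ = 1 the clamped mass is of
order 1 % on spiky histograms — conservation is restored exactly, at the
cost of an equally small multiplicative shrinkage of the peaks). A
mass-conserving Gaussian-kernel backend is available behind
`smoother = "gaussian"` for sensitivity checks.

Default bin sizes scale with the dendritic-field diameter —
diameter/15.8 for synapse maps and diameter/24.3 for dendrite maps, which
reproduces the published 9.7 µm and 6.3 µm at a 153.1 µm field — and are
always overridable. Maps are normalized to [0, 1] either independently
(per-cell colour scales) or jointly (to compare relative contributions
across maps).

## Hotspot clustering

`fit_gmm()` is a full-covariance EM with k-means++ seeding, 10 restarts
(best log-likelihood wins), convergence when the relative log-likelihood
change falls below 1e-8, and a trace-scaled diagonal ridge of 1e-6 on
every covariance so fits cannot collapse onto single points. All
randomness flows through an explicit seed. Hard labels are the argmax
responsibility — the CH index is defined on a partition, so soft
responsibilities are collapsed before scoring:

CH = [Σₖ nₖ‖cₖ − c‖² / (K − 1)] / [Σₖ Σᵢ ‖dᵢ − cₖ‖² / (N − K)],

with c the global centroid and cₖ, nₖ the centroid and size of cluster k.
`select_components()` fits K = 2..10 and keeps the largest CH, ties going
to the smaller K (parsimony); K values whose fit failed or left an empty
hard cluster are recorded and skipped. A CH curve whose maximum is below
twice its median is flagged `low_contrast` — the signature of an
unstructured single blob. (The flag is informational: strongly clustered
data can also keep CH high at larger K by splitting true clusters.)

Outliers: the Mahalanobis distance d = √((x − µ)Σ⁻¹(x − µ)ᵀ) is computed
in SD units — the square-rooted form, so that the 3-SD exclusion
threshold has its standard meaning — and a synapse is excluded only when
it exceeds the threshold for *every* component. Per-cluster composition
is then tabulated over the surviving members.

Model-selection design choices that the data could not decide were fixed
once: per-component full covariances (the reported per-component SDs
imply them), CH on hard assignments, and 10 restarts as a compromise
between determinism of the attained optimum and runtime.

## Connectivity statistics

* `amacrine_probability()` — per-synapse amacrine probability from counts
  or from a stated ratio (1.6:1 → p = 0.6154).
* `run_probability(p, N) = p^N` — the geometric null for N consecutive
  amacrine synapses; p⁵ = 8.8 %, p¹⁴ = 0.1 % at the 1.6:1 ratio.
* `find_amacrine_runs()` — synapses are ordered by cumulative arc length
  along each root-to-leaf path and maximal runs of consecutive amacrine
  synapses are reported per path, deduplicated across paths sharing a
  prefix. "Consecutive" is not operationally defined in the source
  material; this per-path reading matches descriptions such as a single
  dendrite carrying 14 consecutive amacrine synapses, and an alternative
  (breaking runs at branch points) would only shorten runs.
* `partner_profile()` — synapses per presynaptic bipolar cell, totals by
  type, and the per-partner histogram.
* `fisher_exact_2x2()` — exact two-sided p by minimum-likelihood
  summation of hypergeometric probabilities (the common convention; a
  doubling rule is available behind `method = "doubling"`).
* `overlap_analysis()` — boundary-inclusive membership (1e-9 µm
  tolerance) of synapses in a reference cell's dendritic hull, distances
  to the hull's area centroid, and shared presynaptic partners.

Morphometry interprets "diameter from hull area" as the equivalent
circular diameter 2√(A/π) (dendritic fields can be asymmetric, so a
diameter derived from area is better defined than a caliper width); soma
and axon nodes are excluded from dendritic hulls; soma diameter is twice
the widest soma disk (a max-disk reading — an average over the soma
profile stack would be the alternative); mode depth uses 1 % bins with
ties resolved toward the shallower bin.

## Orchestration and reproducibility

`run_pipeline()` runs morphometry → synapse proportions → density →
clustering (smooth-role cells) → run/partner statistics → overlap in a
fixed order with per-stage failure isolation. Each stochastic stage draws
from a stream derived from the master seed and the stage name, so adding
a stage never perturbs another stage's draws; reports contain no
timestamps and are byte-identical under a fixed seed.

The numbered scripts under `analysis/` are thin drivers over these
functions: simulate the scene, morphometry, density maps, hotspot
detection, connectivity statistics, full report. Problem sizes are modest
by design — scenes of ~5,000 nodes and ~1,400 synapses, 126-synapse
clustering problems, 20-scene recovery sweeps — matching the scale of the
source material (one smooth cell with 126 ribbon synapses; three parasols
with 559).

## Numerical and degenerate-input conventions

* Pooled-variance two-sample t test; zero pooled variance with equal
  means returns p = 1 by convention (p = 0 when the means differ).
* Hulls require ≥3 non-collinear points; collinear inputs raise a
  degenerate-geometry error rather than returning a zero-area polygon.
* CH with zero within-cluster dispersion returns +Inf with a warning.
* An all-zero density map is left unchanged by normalization.
* Mixtures centred off the skeleton trigger a warning and uniform
  fallback in the generator.
* EM restarts that collapse (empty component or singular covariance) are
  discarded; if every restart collapses, the fit errors.

## Known limitations

* Planar analyses assume monostratified cells; bistratified types would
  need per-stratum splitting first.
* The run-length null treats synapse kinds as independent draws; real
  runs may be spatially autocorrelated, making p^N conservative or not —
  it is a reference value, exactly as used in the source analysis.
* The CH criterion is evaluated on hard assignments; very overlapping
  clusters would make the selected K sensitive to that choice.
* Recovered hotspot positions inherit the cable-sampling bias discussed
  above on sparse dendritic trees.
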