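# hotspotter

Spatial statistics of synaptic input to retinal ganglion cells (RGCs)
reconstructed from volume electron microscopy.

ON smooth monostratified RGCs respond to light in isolated "hotspots"
separated by insensitive "coolspots", while the co-stratifying ON parasol
RGCs have smooth, homogeneous receptive fields. `hotspotter` implements
the anatomical test of that contrast: are the bipolar-cell ribbon
synapses onto a smooth RGC spatially clustered while parasol input is
homogeneous? The package provides

* a data model and CSV/JSON/SWC I/O for annotation-disk skeletons and
  synapse tables;
* a synthetic reconstruction generator (self-avoiding space-filling
  dendritic growth, planted Gaussian synapse clusters, multinomial
  presynaptic types) so every stage has a ground-truth oracle;
* mass-conserving smoothed 2D density maps (second-order Whittaker
  smoother, λ = 1 by default);
* hotspot detection: full-covariance Gaussian-mixture fits over
  K = 2..10, Calinski–Harabasz model selection

  CH = [Σ_k n_k‖c_k − c‖² / (K−1)] / [Σ_k Σ_i ‖d_i − c_k‖² / (N−K)],

  Mahalanobis outlier exclusion (d = √((x−µ)Σ⁻¹(x−µ)ᵀ) > 3 SD from every
  cluster), and per-cluster presynaptic-type composition;
* convex-hull morphometry (equivalent diameter 2√(A/π), area centroid),
  soma diameters, and inner-plexiform-layer depth profiles (mean and
  binned mode, 0 % = INL/IPL, 100 % = IPL/GCL);
* connectivity statistics: amacrine/bipolar proportions, the geometric
  run null p^N for N consecutive amacrine synapses, arc-length-ordered
  run detection along dendrites, synapses-per-partner profiles, Fisher's
  exact 2×2 test, and parasol-field overlap analysis.

## Worked example

```r
library(hotspotter)

# one smooth RGC with four planted hotspots + three parasols in its field
scene <- generate_paired_scene(
  smooth_skeleton_config(1),
  list(parasol_skeleton_config(2, soma_center = c(-45, 0)),
       parasol_skeleton_config(3, soma_center = c(0, 0)),
       parasol_skeleton_config(4, soma_center = c(45, 0))),
  smooth_synapse_model(5))

rib <- subset_synapses(scene, "smooth_1", kind = "ribbon")
sel <- select_components(cbind(rib$x_um, rib$y_um),
                         k_min = 2, k_max = 10, seed = 6)
sel$model
#> <cluster_model> K = 4, logLik = -1042.57, CH = 868.25
#>   1: weight 0.274, mean (37.9, -38.8), sd (7.7, 7.8)
#>   2: weight 0.210, mean (40.1, 38.7), sd (10.3, 9.7)
#>   3: weight 0.185, mean (-39.2, 39.6), sd (8.0, 9.8)
#>   4: weight 0.331, mean (-41.0, -40.5), sd (7.7, 7.2)

dendritic_field_hull(get_reconstruction(scene, "smooth_1"))
#> <hull_metrics> area 18171.1 um^2, equivalent diameter 152.1 um, centroid (-0.0, -0.0)
```

The selected model has four components (the planted count), each mean
within a few µm of a planted centre at (±38, ±38), with SDs near the
planted 8 µm; the smooth cell's dendritic field is ≈152 µm across versus
≈56 µm for the parasols. With the 1.6:1 amacrine:bipolar ratio the
geometric null gives

```r
p <- amacrine_probability(ratio = c(1.6, 1))
100 * run_probability(p, 5)    # 8.825  -> "8.8 %"
100 * run_probability(p, 14)   # 0.112  -> "0.1 %"
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic
scene and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # scene + planted truth
Rscript analysis/02_morphometry.R     # fields, somas, depths, t tests
Rscript analysis/03_density_maps.R    # smoothed density maps
Rscript analysis/04_hotspots.R        # GMM + CH selection + composition
Rscript analysis/05_connectivity.R    # runs, partners, Fisher, overlap
Rscript analysis/06_pipeline_report.R # orchestrated report.json
```

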