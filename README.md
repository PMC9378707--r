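# cranioform

Dense-correspondence ("homologous") cranial surface modelling in R, for
geometric morphometricians and biological anthropologists who want
landmark-guided template fitting and whole-surface statistics without
leaving the R ecosystem.

Classical craniometrics reduces a skull to a few dozen inter-landmark
distances. A homologous model instead represents every specimen by the
*same* triangle mesh — one template deformed onto each surface scan — so
that vertex *k* marks the same anatomical location on every specimen. The
whole configuration of thousands of vertices then becomes an ordinary
multivariate observation, and familiar tools (PCA, ROC, regression) apply
to entire cranial surfaces.

## What the package does

1. **Synthetic anatomy** (`make_template()`, `sample_population()`):
   a smooth, bilaterally symmetric cranium-like template (ellipsoidal
   vault, facial block, zygomatic ridges; cranial base removed, leaving a
   boundary loop) carrying 56 named craniometric landmarks, and a
   generator of scan populations with known ground truth: a size mode, a
   vault length/breadth mode, a facial projection mode and a facial height
   mode, group mean offsets, smooth per-specimen surface noise, and
   analytically placed landmarks. Every scan gets its own triangulation,
   so correspondence must be established by fitting, never by copying
   indices.
2. **Template fitting** (`fit_homologous()`): rigid landmark
   initialisation (Kabsch), then non-rigid ICP in the style of Amberg's
   optimal-step scheme — one 3×4 affine transform per template vertex,
   minimising

   `E(X) = γ E_stiffness + α E_data + β E_landmark`

   where `E_stiffness` penalises differences between neighbouring
   per-vertex transforms, `E_data` is the squared distance of each vertex
   to its closest compatible point on the scan (exact point-to-triangle,
   BVH-accelerated, with distance and normal-angle rejection), and
   `E_landmark` pins the 56 landmark vertices. Three coarse passes with
   decreasing stiffness are followed by one Loop subdivision and a fine
   pass, and the result is expressed in the Frankfurt-based head frame
   (`compute_head_frame()`). Typical fit quality on synthetic scans:
   mean landmark residual < 0.01 mm, mean vertex-to-surface residual well
   under 0.322 mm.
3. **Shape space** (`fit_shape_pca()`): covariance PCA of the N × 3V
   table of flattened vertex coordinates (dual/Gram form, N − 1
   convention), on raw and centroid-size-normalised data; per-coordinate
   loadings as Pearson correlations, colour maps of high-loading zones,
   ±3 SD virtual shapes, morph sequences and group-average models.
4. **Discrimination** (`one_vs_rest_scan()`): one-vs-rest ROC per group
   and component; AUC as the normalised Mann-Whitney U (ties ½), with
   Hanley–McNeil standard errors and a χ²(1) test of AUC = 0.5;
   representative-specimen selection by Euclidean distance to the
   population mean.
5. **Allometry** (`allometry_scan()`): the power law `Y = a X^b` fitted
   as `log Y = b log X + log a` by least squares, where X is centroid
   size and Y a component score shifted positive by the
   `round(|min|) + 1` rule; two-tailed t-test on b with n − 2 df.
6. **Pipeline** (`run_study()`, `inst/cli/cranioform.R`): a config-driven
   end-to-end runner emitting homologous PLYs, QC, PCA/score tables,
   colour-map and virtual-shape meshes, ROC and allometry tables, and a
   run log of every resolved convention.

Statistical tables are tibbles with `tidy()` / `glance()` / `autoplot()`
methods; meshes are a light S3 `triangle_mesh` with PLY (ASCII and binary
little-endian, per-vertex RGB) and OBJ I/O.

## Worked example

```r
library(cranioform)

template <- make_template()                     # 4473 vertices, 56 landmarks
pop <- population_spec(n_groups = 2, n_per_group = 5,
                       resolution = 20000, seed = 42)
dat <- sample_population(pop)

models <- Map(function(scan, lms, id)
                fit_homologous(template, scan, scan_lms = lms, id = id),
              dat$scans, dat$landmarks, names(dat$scans))
models[[1]]
#> <homologous_model> S001: 17785 vertices, CS 10679.4 mm,
#>   landmark 0.002381 mm, surface 5.601e-05 mm

space <- fit_shape_pca(build_shape_table(models, groups = dat$truth$group))
tidy(space)
#> # A tibble: 9 × 4
#>   component eigenvalue contribution_pct cumulative_pct
#> 1         1    347254.           80.4             80.4
#> 2         2     64802.           15.0             95.4
#> 3         3     14762.            3.42            98.8
#> 4         4      4017.            0.930           99.8

cor(space$scores[, 1], dat$truth$size)
#> 0.865        # PC1 of the non-normalised run is the size axis
```

The per-model line reports fit QC: the mean distance between fitted
landmark vertices and their targets (0.0024 mm) and the mean distance from
the 17,785 model vertices to the scan surface (≈ 6e-05 mm). In the PCA
table, PC1 carries 80% of the variance in this tiny two-group batch and
correlates 0.87 with the generator's true size coefficient (n = 10; the
correlation exceeds 0.9 at study sizes, see the test suite). ROC and
allometry scans continue from the fitted space:

```r
one_vs_rest_scan(space, min_n = 5)          # AUC + chi-square per (group, PC)
allometry_scan(space, centroid_sizes = vapply(models, `[[`, 0, "centroid_size"))
```

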