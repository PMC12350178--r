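# organoidmorph

Quantification toolkit for liver organoid and assembloid imaging. It serves
two measurement problems that come up when hepatocyte organoids are grown
alone or assembled with cholangiocytes and portal mesenchyme:

1. **Does a structure change shape over time?** Brightfield/actin time-lapse
   outlines are scored with a temporal extension of the smooth Euler
   characteristic transform (SECT): each outline becomes a directions ×
   thresholds matrix of centred, integrated Euler characteristic curves

   *s(θ, t) = ∫ ( χ{x ∈ P : ⟨x, v(θ)⟩ ≤ u} − χ̄(θ) ) du*,

   and a series is summarized by the distance ratio **d₁/d₀**, where d₀ is
   the first frame's descriptor magnitude and d₁ the rotation-aligned
   distance between final and first frame. Static structures score ≈ 0;
   fibrotic compaction scores ≈ 1. The same descriptors separate the two
   organoid morphology classes — smooth spheres ("ball") versus lobed,
   folded structures ("bubbly/grape-like") — by distance-based clustering.

2. **How is the bile-canaliculi network organized?** Two-channel 3D stacks
   (apical marker + cortical actin, isotropic 0.3 µm voxels) run through
   median filtering, per-channel IsoData thresholding, channel overlap,
   inflate → fill-holes → deflate lumen completion, size/border object
   filtering, local thickness, and homotopy-preserving skeletonization; the
   largest connected network per structure is summarized by total branch
   length, triple/quadruple junction counts, and per-branch mean diameters
   in 0.25 µm bins.

A fibrillar-collagen readout (band-thresholded SHG integrated density inside
a hand-drawn ROI), exact two-tailed Mann–Whitney comparisons, kernel density
curves, and seeded synthetic-data generators (outlines, compaction time
courses, tube-network phantoms with known centreline graphs) round out the
package. Because the imaging data the pipelines target are not publicly
deposited, every stage is validated against the generators' analytic ground
truth and against independent oracles.

## Worked example

```r
library(organoidmorph)

# --- shape change over time -------------------------------------------------
static  <- gen_timecourse("static",     seed = 11, label = "assembloid_A")
control <- gen_timecourse("compacting", shrink = 0.15, seed = 12,
                          label = "assembloid_B")
distance_ratio(build_timecourse(static))
#> DETECT ratio 'assembloid_A' (first_last): d0 = 183.0504, d1 = 0.6493, d1/d0 = 0.0035
distance_ratio(build_timecourse(control))
#> DETECT ratio 'assembloid_B' (first_last): d0 = 182.8520, d1 = 166.9892, d1/d0 = 0.9132
```

`assembloid_A` keeps its shape (ratio 0.0035 — the residual is outline
tracing noise); `assembloid_B` compacts by 15 % per frame and scores 0.91.
Comparing 16 static against 16 compacting structures:

```r
rs <- vapply(1:16, function(s) distance_ratio(build_timecourse(
        gen_timecourse("static", seed = s, label = "o")))$ratio, 0)
rc <- vapply(1:16, function(s) distance_ratio(build_timecourse(
        gen_timecourse("compacting", shrink = 0.15, seed = 100 + s,
                       label = "o")))$ratio, 0)
mann_whitney(rs, rc)
#> Mann-Whitney (two-tailed, exact): U = 0, p = 3.327e-09 (n = 16, 16)
```

```r
# --- bile-canaliculi network from a noisy phantom ---------------------------
g   <- gen_tube_graph(radius = 1.0, seed = 5)   # 10 edges, known junctions
ph  <- gen_tube_phantom(g, snr = 5, seed = 5)   # hollow membranes + noise
res <- run_bc_pipeline(ph$apical, ph$cortical, structure_id = "phantom05")
res
#> bile-canaliculi pipeline result
#>   thresholds: apical 47.7, cortical 49.5
#>   objects kept: 1 (removed: 0 size, 0 border)
#>   networks: 1
#> network_features 'phantom05': length 80.2 um, junctions 3 (2 triple, 1 quadruple), 8 branches
tube_graph_truth(g)$total_length_um
#> [1] 79.5
```

The pipeline recovers the phantom's 2 triple + 1 quadruple junctions exactly
and its 79.5 µm total length within 1 %. The branch diameters land in the
bins around the ground-truth 2.6 µm (tube diameter 2 µm plus the 0.6 µm
membrane the completion step fills):

```r
diameter_histogram(res$features$branch_diameters_um)$percent
#> ... [2.25, 2.50): 50   [2.50, 2.75): 50   (all other bins 0)
```

A thin command-line wrapper (`inst/exec/organoidmorph`) exposes the same
pipelines as `shape score|cluster`, `bcnet run`, `shg quantify` and
`simulate shapes|timecourse|phantom`; every run writes a JSON manifest with
the resolved configuration, inputs and per-stage counts.

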