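# aispuncta

Quantification of punctate immunofluorescence enrichment on the axon
initial segment (AIS), for neuroscientists analysing single-optical-section
confocal images of receptor clusters (e.g. GABA<sub>A</sub> receptor
α-subunits) co-labelled with the AIS marker ankyrin-G.

Receptor clusters appear as small suprathreshold blobs ("puncta"). The
package measures, per region of interest (ROI), the cluster density,
mean size and percent area, and summarizes the AIS aggregation of a
subunit in a brain area by the **enrichment ratio**

```
E = mean percent area over AIS ROIs / mean percent area over congruent non-AIS ROIs
```

where each AIS ROI is paired with a contour-congruent control region in
the surrounding neuropil. The full chain is:

1. rolling-ball background subtraction (grayscale opening by a
   spherical-cap element, default radius 50 px at ~64 nm/px);
2. triangle auto-thresholding (256-bin histogram, peak-to-tail chord);
3. connected-component particle analysis gated to 0.05–10.00 µm² area
   and 0.10–1.00 circularity (4πA/P², chain-code perimeter);
4. per-ROI morphometry with the zero-puncta rule (density 0, size
   missing);
5. the enrichment ratio and its distributional auxiliaries;
6. ROI-restricted colocalization: Pearson's r (optionally above Costes
   auto-thresholds) and binary Manders M1/M2;
7. inference: two-way ANOVA (location × brain area, Type III), Bonferroni
   planned comparisons, one-way ANOVA with Tukey–Kramer post-hocs,
   Bonferroni-corrected t-tests for coefficient families.

A synthetic-scene generator (`generate_scene()`) plants curved AIS
trajectories with beads-along-a-string puncta, congruent translated
control regions, partner channels with controlled apposition probability,
background gradients and Poisson+Gaussian noise — with exact ground-truth
tables — so every stage is testable without external data. See the
vignette `vignettes/aispuncta-methods.Rmd` for the model, parameter and
validation details.

## Worked example

```r
library(aispuncta)

# a 512x512 scene at 64 nm/px: 6 AIS ribbons at 30 puncta/100 um^2,
# congruent controls at 10 -> planted enrichment ratio ~ 3
cfg <- scene_config(image_size_px = c(512L, 512L), n_ais = 6L,
                    ais_length_um = 12, seed = 5L)
sc  <- generate_scene(cfg)
sc
#> <ais_scene> 512x512 px, channels: alpha2, AnkG; 12 ROIs, 101 puncta
#>   planted enrichment ratio: 2.702

res <- run_quantify(list(scene = cfg, channel = "alpha2",
                         preprocess = list(rolling_ball_radius_px = 12)))
res$enrichment
#>     brain_area n_ais_rois n_nonais_rois mean_pct_area_ais mean_pct_area_nonais enrichment_ratio
#> BLA        BLA          6             6          7.075119             2.613633         2.707006
```

The planted ratio for this seed is 2.702 (the realized value after
stochastic placement of a 30:10 density contrast); the pipeline recovers
2.707 from the rendered noisy image. `res$roi_stats` holds the per-ROI
table (density per 100 µm², mean cluster size in µm², percent area), and
`res$comparisons` the AIS vs non-AIS Bonferroni t-tests.

A thin command-line wrapper with `simulate | quantify | coloc`
subcommands is installed at `inst/cli/aispuncta.R`.

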