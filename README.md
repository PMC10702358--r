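# gelbead

Quantitative readout for droplet-microfluidic invasion assays in which
cancer cells are encapsulated in ~100 µm Matrigel beads (a basement
membrane mimic) and embedded in collagen I (a stromal mimic). Whether
such an assay works — and whether its biology is interpretable — hangs
on three measurements, and gelbead computes all three from raw imagery
or tables:

1. **Droplet metrology.** Droplets in bright-field channel videos are
   detected with a circular Hough transform (gradient voting plus
   sub-pixel circle-fit refinement), tracked across frames, and counted
   once each as they cross the frame's centre line. The size summary
   reports the count *N*, mean diameter *D*~av~, and dispersity
   **Ð = sd / D~av~** — the monodispersity metric.
2. **Encapsulation statistics.** Cell occupancy per droplet follows the
   Poisson law **P(k) = λ^k e^(−λ) / k!** with λ the mean cells per
   droplet. The package fits λ, compares observed 0/1/2/3+ bins against
   the model (chi-square), converts between λ and the fraction of
   occupied droplets (1 − e^(−λ)), and does the throughput and loading
   arithmetic: generation rate = Q / (πD³/6), cell-bearing rate,
   nominal λ from cell density, and dilution.
3. **3D invasion quantification.** Nuclei in anisotropic confocal
   stacks are segmented by z-interpolation → Gaussian smoothing →
   global Otsu threshold → exact anisotropic Euclidean distance
   transform → marker-controlled watershed, with oversized regions
   (> 2× the average volume) split. The bead centre is estimated from
   the mean nucleus position; a cell is *invaded* when its distance
   from the bead surface exceeds its sphere-equivalent radius
   r = (3V/4π)^(1/3). Reports carry n_b (resident cells), n_i (invaded
   cells), d_max (maximum invasion distance) and percent invaded, and
   conditions are compared by pooled t-tests plus Tukey–Kramer.

Seeded generators (`simulate_droplet_video()`, `simulate_occupancy()`,
`simulate_confocal_stack()`) produce synthetic inputs with exact ground
truth for every stage, including a compound-Poisson "aggregated" loading
mode that reproduces the excess of 3+-cell droplets caused by cell
clumping.

The package is tidyverse-native: analysis functions take data frames and
return tibbles, fitted objects have `tidy()` / `glance()` methods, and
each result type has an `autoplot()`.

## Worked example

```r
library(gelbead)

# --- droplet sizing on a synthetic channel video --------------------
vid    <- simulate_droplet_video(n_droplets = 50, seed = 7)
dets   <- detect_droplets(vid$frames, radius_range = c(15, 35))
tracks <- count_center_crossings(link_tracks(dets, max_displacement = 20))
summarize_sizes(tracks)
#> <size_summary> N = 50 counted droplets
#>   D_av = 100.39 um, sd = 2.85 um, dispersity = 2.83%

# --- Poisson occupancy ----------------------------------------------
occ <- simulate_occupancy(20000, lambda = 0.3, seed = 7)
fit <- fit_poisson(occ)
fit
#> <occupancy_fit> n = 20000 droplets, lambda = 0.2989 (estimated)
#>   chi-square = 0.707 on 2 df, p = 0.702

throughput_estimate(1, 100, occupancy = 0.16)
#> # A tibble: 1 × 3
#>   droplet_rate_per_min occupancy_fraction cell_bearing_rate_per_min
#>                  <dbl>              <dbl>                     <dbl>
#> 1                1910.               0.16                      306.

# --- 3D invasion quantification -------------------------------------
sim <- simulate_confocal_stack(n_inside = 56, n_invaded = 9,
                               invasion_distances_um = c(10, 16), seed = 7)
rep <- quantify_invasion(sim$stack, bead_radius_um = 50)
rep
#> <invasion_report> n_b = 56, n_i = 9 (14% invaded), d_max = 17.5 um
```

Reading the output: all 50 simulated droplets were found and counted
once (N = 50); the recovered mean diameter and dispersity (100.4 µm,
2.8 %) match the generator's 100 µm / 3 % CV ground truth. The
occupancy fit recovers λ ≈ 0.299 from data generated at λ = 0.3 and the
chi-square finds no departure from Poisson loading (p = 0.70). At a
16 % occupancy, ~1910 droplets/min yield ~306 cell-bearing beads/min.
The confocal pipeline recovers all 65 nuclei, classifies exactly the 9
displaced ones as invaded (14 % of cells), and reports the maximum
surface distance.

A command-line wrapper over the same functions ships in
`inst/scripts/gelbead-cli.R` with subcommands `size-droplets`,
`fit-poisson`, `throughput`, `quantify-invasion`, `compare-conditions`
and `simulate`; every run writes a JSON manifest echoing its resolved
configuration.

See `vignettes/gelbead-methods.Rmd` for the models, parameter defaults,
numerical choices and limitations.

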