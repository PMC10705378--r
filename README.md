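# monorecruit

Analysis toolkit for monocyte trafficking in microfluidic vascularized tumor
models ("tumor-on-chip"). It answers two questions these assays pose:

1. **Where are the monocytes?** From a two-channel confocal max-projection
   (vasculature + labelled monocytes) of a microvascular bed surrounding a
   central tumor well, every detected cell is classified as **luminal**
   (inside a vessel lumen), **extravasated** (in the gel, outside vessels)
   or **recruited** (inside the tumor well), giving per-field compartment
   counts and a recruited fraction trackable over days.
2. **Why do they move?** From endpoint cell positions in a unidirectional
   gel-channel migration assay, the one-dimensional Keller–Segel model

   ∂n/∂t = ∂/∂x ( D ∂n/∂x − χ n ∂c/∂x )

   is fit on the device geometry (zero-flux walls, all cells starting at the
   entry interface): the random-motility coefficient **D** (µm²/h) is
   estimated from no-chemoattractant controls, pooled, and frozen; the
   chemotaxis coefficient **χ** (µm²/h per unit normalized concentration)
   is then fit per condition by binned multinomial maximum likelihood. A
   three-arm comparison (control / uniform conditioned media / gradient)
   separates true chemotaxis from chemokinesis, i.e. directed drift from
   uniformly elevated motility.

Because raw microscopy from such experiments is rarely shareable, the
package ships seeded synthetic generators — vascular-bed images with
per-cell ground-truth labels, and biased-random-walk migration snapshots
with known (D, χ) — so every stage is verifiable end to end. Intended users
are labs running vascularized-tumor or gel-channel chemotaxis assays who
want a scripted, reproducible replacement for interactive image-analysis
macros plus a principled motility analysis.

## Worked example

```r
library(monorecruit)

# --- compartment quantification on a synthetic field ---
geom <- ivas_geometry(pixel_size_um = 3)        # 3 x 3 mm bed, 1.5 mm well
b <- generate_vessel_image(geom, n_luminal = 30, n_extravasated = 40,
                           n_recruited = 30, snr = 10, seed = 7)
res <- quantify_image(b$image[, , 1], b$image[, , 2],
                      quant_config(pixel_size_um = 3))
res$counts
#> Compartment counts: 30 luminal, 38 extravasated, 32 recruited (total 100)
#>   recruited fraction: 0.320

# --- chemotaxis coefficient from a simulated day-1 endpoint ---
mg <- migration_geometry()                       # 1300 um gel channel
conc0 <- make_concentration(mg, "zero")
concg <- make_concentration(mg, "linear_gradient")

ctrl <- simulate_migration(ks_parameters(D_um2_per_h = 1000), conc0, mg,
                           n_cells = 5000, times_h = 24, seed = 1)[[1]]
fD <- estimate_D(ctrl, mg, estimator = "likelihood")
fD$estimate
#> [1] 1012.899

grad <- simulate_migration(ks_parameters(1000, chi_um2_per_h = 13000),
                           concg, mg, n_cells = 5000, times_h = 24,
                           seed = 2)[[1]]
fc <- estimate_chi(grad, D_fixed = fD$estimate, conc = concg, geometry = mg)
c(chi = fc$estimate, drift_um_per_h = fc$effective_drift_um_per_h)
#>            chi drift_um_per_h
#>   12783.951627       9.833809
```

The recovered counts match the generator's ground truth (30/40/30) within a
few cells, D̂ is within ~2% of the true 1000 µm²/h, and χ̂ within ~3% of the
true 13000 µm²/h — a drift of ~10 µm/h up the gradient.

The numbered scripts under `analysis/` run the same pipeline as a
narrative: `01_generate_images.R` → `02_quantify_recruitment.R` (day 1–3
recruitment time course with QC overlays) and `03_simulate_migration.R` →
`04_fit_chemotaxis.R` → `05_chemokinesis_screen.R` (assay simulation,
coefficient fits, chemotaxis-vs-chemokinesis report), writing their tables
under `results/`. `run_demo(seed, out_dir)` runs a compact seeded
end-to-end workflow in one call.

See the vignette (`vignettes/monocyte-recruitment-and-chemotaxis.Rmd`) for
the models, parameter defaults, numerical scheme and limitations.

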