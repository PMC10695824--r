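# borealbedo

Forest composition change and its albedo-driven radiative forcing, as a
tested R pipeline for boreal landscapes.

## What it does, and for whom

Stand-replacing boreal wildfires replace evergreen conifers with brighter
early-successional deciduous stands; decades later the conifers close back
in. Because deciduous canopies — especially leafless ones over spring
snow — raise surface albedo, this successional mosaic perturbs the
shortwave energy balance. `borealbedo` is for landscape ecologists and
remote-sensing scientists who want to quantify that chain end to end:

1. map **sub-pixel deciduous fraction** `d` and **tree canopy cover** `c`
   from seasonal multispectral composites with ensemble regression trained
   on forest-inventory basal areas (response `d = BA_dec / BA_total`),
   with per-pixel uncertainty from the spread of ensemble leaf samples;
2. model **seasonal albedo** `alpha(d, c)` from the two composition maps;
3. convert the epoch-to-epoch albedo change into **shortwave radiative
   forcing** with a radiative kernel `K` (W m^-2 per unit albedo,
   negative): `F = (alpha_end - alpha_start) * K`, so an albedo increase
   yields cooling;
4. stratify changes and forcings by **fire-age chronosequence** classes
   (old 1950–1978, intermediate 1979–1998, recent 1999–2018), fire
   perimeters, and regions, with exact area accounting in Mha.

A seeded synthetic-landscape generator (post-fire succession dynamics,
endmember mixture reflectance, plot tables, coarse albedo, negative
kernels) stands in for satellite/inventory archives, so the whole pipeline
is testable offline; the real-data path reads the same raster/vector
contracts. See `vignettes/boreal-composition-albedo.Rmd` for the models
and every numerical choice.

## Worked example

```r
library(borealbedo)

cfg <- default_pipeline_config(grid_shape = c(128L, 128L), seed = 11)
cfg$n_plots <- 800L
run <- run_pipeline(cfg, outdir = "demo_artifacts")
print(run)
subset(run$report,
       select = c(stratum, n_pixels, dec_delta_mean, spring_forcing_mean))
```

prints (elapsed about 2 min on one CPU):

```
<borealbedo_run> 128 x 128 landscape, epochs 2000-2015
  deciduous fraction: validation r2 0.562 rmse 0.117 (vs truth r2 0.729 rmse 0.090)
  canopy cover:       validation r2 0.988 rmse 0.031 (vs truth r2 0.992 rmse 0.024)
  report: 5 strata rows
       stratum n_pixels dec_delta_mean spring_forcing_mean
1       domain    14531    -0.03092850           0.5772799
2 intermediate      631    -0.06929314          10.8607503
3          old     7729    -0.10975732           5.0256723
4       recent     3956     0.09054864          -9.0893772
5    fires_all    12316    -0.04331189           0.7886941
```

Reading this: the deciduous-fraction map recovers the true field with
held-out RMSE 0.090 (r^2 0.73); recently burned pixels gained deciduous
fraction (+0.09) and their spring forcing is strongly negative (cooling,
-9.1 W m^-2) because their albedo rose, while intermediate- and old-age
burns warm (+10.9 and +5.0 W m^-2) as canopy regrowth darkens them; the
domain-wide net is near neutral (+0.6 W m^-2) — the recent-cooling /
older-warming cancellation that the chronosequence stratification is
designed to expose. `demo_artifacts/`
then holds the cover and forcing rasters (ENVI float32 + header), the
change report (CSV/JSON), fire perimeters (GeoJSON) and an md5 manifest.

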