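# Bundled demo study: a 60 x 60 km synthetic grassland landscape with a
# three-landscape conservation network and two simulated species -- one
# concentrated in grass-rich habitat and one spatially uniform.
seed: 42

landscape:
  extent: [600, 600]        # fine cells (rows, cols)
  fine_cellsize: 100        # m
  coarse_cellsize: 1000     # m (1-km2 analysis cells)
  class_fractions:
    grassland: 0.30
    agriculture: 0.40
    forest: 0.22
    urban: 0.08
  autocorrelation_range: 3000   # m

network:
  n_focal: 3
  gbcas_per_focal: 3
  focal_area_km2: 150
  gbca_area_km2: 6

survey:
  n_sites: 400
  season: [140, 190]        # day-of-year window
  buffer_radius_m: 100

model:
  abund: [grassland, agriculture, urban, tmax, precip]
  det: [jdate]
  offset_area_km2: 0.031415926535   # area of a 100-m-radius circle, km2
  J: 5                              # five 2-min removal bins

species:
  - name: hotspot
    # grassland-concentrated species (densities per km2, log link)
    beta_abund: {intercept: 1.1, grassland: 2.0, agriculture: 0.0,
                 urban: -0.6, tmax: 0.15, precip: 0.1}
    beta_det: {intercept: 0.0, jdate: -0.2}
  - name: uniform
    # spatially uniform species: intercept-only abundance
    beta_abund: {intercept: 0.8}
    beta_det: {intercept: 0.3}
    abund: []

rtr:
  n_replicates: 1000
  quantile: 0.90
  unsuit_frac: 0.20

scenarios: [focal_vs_state, gbca_vs_state, gbca_vs_focal]
targets: [0.20, 0.10]

validation:
  gof_nboot: 30
  auc_reps: 5
  crossval: true
  moran: false
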