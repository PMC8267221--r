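# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code under fixed seeds; sizes are kept small for
# the unit tests (the acceptance tests build their own larger volumes).

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fix)) assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

# three flat structural layers, no vessels; fits the 384-sample depth range
layers3 <- function() {
  data.frame(name = c("L1", "L2", "L3"),
             depth_um = c(80, 150, 250),
             thickness_um = c(20, 40, 30),
             reflectivity = c(0.8, 0.4, 0.9))
}

no_vessels <- function() {
  data.frame(name = character(), depth_um = numeric(),
             target_density_pct = numeric())
}

small_header <- function(n_samples = 384L, n_ascans = 48L, n_bscans = 2L,
                         n_repeats = 2L, lambda_nonlin = 0) {
  phantom_header(n_samples = n_samples, n_ascans = n_ascans,
                 n_bscans = n_bscans, n_repeats = n_repeats,
                 lambda_nonlin_nm = lambda_nonlin)
}

# reconstructed 3-layer structural phantom (no vessels, no dispersion)
layered_recon <- function() {
  fixture("layered_recon", function() {
    h <- small_header()
    ph <- generate_raw_spectra(
      phantom_spec(layers = layers3(), vessel_layers = no_vessels(),
                   noise_sigma = 2, seed = 101), h)
    list(header = h, phantom = ph, vol = reconstruct_volume(ph$volume))
  })
}

# small euthermic vessel phantom: one plexus, 4 repeats
vessel_recon <- function() {
  fixture("vessel_recon", function() {
    h <- phantom_header(n_samples = 384L, n_ascans = 48L, n_bscans = 48L,
                        n_repeats = 4L)
    spec <- phantom_spec(
      layers = layers3(),
      vessel_layers = data.frame(name = "MCP", depth_um = 150,
                                 target_density_pct = 22),
      flow_fraction = 0.9, noise_sigma = 3, seed = 201)
    ph <- generate_raw_spectra(spec, h)
    list(header = h, phantom = ph, vol = reconstruct_volume(ph$volume))
  })
}

# mean FSADA decorrelation at the vessel voxels of one B-scan, given a raw
# phantom volume reconstructed without registration
vessel_voxel_decorrelation <- function(ph, vol, bscan) {
  truth <- ph$truth
  sc <- bm_scan(vol$amplitude[, , bscan, ], vol$repetition_time_ms)
  d <- fsada(sc)$decorrelation
  rows <- truth$vessel_rows[[1L]]
  cols <- which(truth$vessel_masks[[1L]][bscan, ])
  mean(d[rows, cols])
}

expect_error_matching <- function(expr, pattern) {
  expect_error(expr, regexp = pattern)
}
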