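# Shared fixtures, built in code at test time.

default_grid <- make_energy_grid()

default_spectrum <- function(params = beam_model_params(),
                             grid = default_grid)
  generate_beam_spectrum(grid, params)

# a random spectrum over a fresh grid, flux/current drawn uniformly
random_spectrum <- function(n_bins = 200L, seed = 1L) {
  set.seed(seed)
  g <- make_energy_grid(1e-3, 1e7, n_bins)
  flux <- runif(n_bins, 0, 1e7)
  beam_spectrum(g, flux, runif(n_bins, 0, 1) * flux,
                gamma_dose_rate = runif(1, 0, 1e-3),
                fast_dose_rate = runif(1, 0, 1e-3))
}

# coarse phantom keeps the voxel count small for fast tests
coarse_phantom <- cylinder_phantom_spec(voxel_size = 1)

table3_tumor <- tissue_composition("tumor", 52.5, 1, 2.2, 5.3)
table3_skin <- tissue_composition("skin", 22.5, 1, 2.5, 2.5)
table3_kidney <- tissue_composition("kidney", 75, 1, 3.2, 1.3)
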