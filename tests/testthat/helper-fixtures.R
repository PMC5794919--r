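# Shared fixtures, built once per test run. Small grids keep the suite
# fast; the full-size defaults are exercised in the acceptance tests.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, make) {
    if (!exists(name, envir = cache)) assign(name, make(), envir = cache)
    get(name, envir = cache)
  }
})

fx_spec <- function() fx("spec", function()
  phantom_spec(14.0, seed = 7L))

fx_phantom <- function() fx("phantom", function()
  make_hand_phantom(fx_spec()))

fx_maps4 <- function() fx("maps4", function()
  make_coil_maps(4, seed = 3L))

fx_kspace <- function() fx("kspace", function()
  simulate_kspace(fx_phantom(), fx_maps4(), noise_sigma = 0, seed = 5L))

fx_kspace_noisy <- function() fx("kspace_noisy", function()
  simulate_kspace(fx_phantom(), fx_maps4(), noise_sigma = 0.02, seed = 5L))

fx_full_pattern <- function() fx("full_pattern", function()
  caipirinha_pattern(c(64L, 16L), 1L, 1L, 0L, 12L, AF_nominal = 1))

# small 2D-slice setup for solver tests (single z slice)
fx_slice <- function() fx("slice", function() {
  sp <- phantom_spec(13.0, grid_shape = c(64L, 64L, 1L),
                     voxel_size = c(0.45, 0.45, 0.9), n_bones = 3L,
                     seed = 11L)
  ph <- make_hand_phantom(sp)
  maps <- make_coil_maps(4, grid_shape = c(64L, 64L, 1L),
                         voxel_size = c(0.45, 0.45, 0.9), seed = 12L)
  list(spec = sp, phantom = ph, maps = maps,
       kspace = simulate_kspace(ph, maps, 0, seed = 13L))
})

rand_cx_array <- function(dims, seed) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
        dims)
}

with_seed_local <- agesim:::with_seed
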