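# fixtures are generated in code; heavyweight builds are cached per session
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

make_centers <- function(n, seed = 1, noise = 0.15, spacing = 12) {
  generate_hex_patch(patch_spec(n, spacing = spacing, noise_amplitude = noise,
                                seed = seed))
}

# a 7-cell rosette with perfect hexagonal symmetry
rosette_centers <- function(spacing = 12) {
  generate_hex_patch(patch_spec(7, spacing = spacing, noise_amplitude = 0))
}

small_monolayer <- function() {
  fixture("ml20", build_monolayer(make_centers(20, seed = 3, noise = 0.2)))
}

# standard wounded study conditions: 80-cell patch, 5 central cells ablated
std_patch <- function(seed = 1) {
  key <- paste0("std", seed)
  fixture(key, {
    cen <- make_centers(80, seed = seed)
    list(centers = cen, ablated = select_ablation_region(cen, 5))
  })
}
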