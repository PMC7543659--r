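# Shared fixtures, memoized so expensive scenes are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small noisy scene on a 32^3 grid (fast; used across modules)
small_scene <- function() fixture("small_scene", function() {
  model <- make_toy_model(60, "blob", box = 32 * 1.2, seed = 5)
  make_scene(model, c(32, 32, 32), 1.2, d_min = 2.6,
             noise_profile(3.2), seed = 7)
})

# noise-free compact scene on a 16^3 grid with exactly flat solvent
flat_scene <- function() fixture("flat_scene", function() {
  model <- make_toy_model(8, "helix", box = 16 * 1.5, seed = 3)
  make_scene(model, c(16, 16, 16), 1.5, d_min = 4, profile = NULL, seed = 1)
})

# flat-solvent prior with known solvent (mean 0, sd at floor) and a broad,
# essentially uninformative macromolecule component
flat_solvent_prior <- function(scene) {
  mask <- scene$solvent_mask_true
  structure(list(
    solvent = c(mean = 0, sd = 1e-8),
    macro = tibble::tibble(weight = 1,
                           mean = mean(scene$truth$values[mask$values]),
                           sd = 100),
    region_mask = mask, sigma_floor = 1e-8), class = "densityprior")
}

# default full-size scene of the study conditions (64^3, 1.2 A voxel,
# ~150-atom motif, nominal resolution 3.5 A)
default_scene <- function(seed = 1) {
  fixture(paste0("default_scene_", seed), function() {
    model <- make_toy_model(150, "blob", box = 64 * 1.2, seed = 10 + seed)
    make_scene(model, c(64, 64, 64), 1.2, d_min = 2.5,
               noise_profile(3.5), seed = seed)
  })
}

default_params <- function(scene, seed = 1) {
  denmod_params(resolution = 3.5, d_min = 2.5,
                fraction_macromolecule = mean(scene$solvent_mask_true$values),
                seed = seed)
}

half_average <- function(scene) {
  with_values(scene$truth, (scene$half_a$values + scene$half_b$values) / 2)
}

random_map <- function(dims = c(16, 16, 16), voxel = 1, seed = 1, sd = 1) {
  set.seed(seed)
  map_grid(array(stats::rnorm(prod(dims), sd = sd), dims), voxel)
}
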