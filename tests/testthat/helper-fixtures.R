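# small builders shared across test files

tiny_grid <- function(shape = c(6, 6, 6), spacing = 1.5) {
  image_grid(shape, spacing = spacing)
}

# minimal valid cohort with both groups and >= 2 scanners
toy_cohort <- function(n_cs = 5, n_nc = 7, n_scanners = 2, seed = 1) {
  set.seed(seed)
  n <- n_cs + n_nc
  validate_cohort(tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("CS", "NC"), c(n_cs, n_nc)),
    age = round(rnorm(n, 55, 7), 1),
    gender = sample(c("male", "female"), n, replace = TRUE),
    scanner = paste0("sc", 1 + (seq_len(n) %% n_scanners)),
    tiv = rnorm(n, 1.45e6, 1e5)
  ))
}

# a design whose planted contrast is null everywhere
null_design <- function(...) {
  simulation_design(effects = list(), ...)
}

# one planted VPL effect, slopes (2, 1), defaults otherwise
effect_design <- function(noise_sd = 1, ...) {
  simulation_design(noise_sd = noise_sd, ...)
}

full_mask <- function(grid) rep(TRUE, prod(grid$shape))

# simulate, build the default VPL-ipsi design, and return the pieces used
# by most pipeline tests
sim_fit_pieces <- function(design, seed) {
  sim <- simulate_cohort(design, seed = seed)
  am <- lesion_exclusion_mask(full_mask(sim$stack$grid), sim$lesions)
  sv <- seed_volumes(sim$volumes, sim$cohort, "VPL", "ipsi")
  scn <- build_scn_design(sim$cohort, sv, seed_name = "VPL_ipsi")
  list(sim = sim, mask = am, seedvol = sv, design = scn)
}

# paint a logical blob mask on a grid from 1-based index ranges
paint_mask <- function(grid, i, j, k) {
  m <- array(FALSE, grid$shape)
  m[i, j, k] <- TRUE
  m
}

# linear voxel indices of a box
ijk_box <- function(grid, i, j, k) which(paint_mask(grid, i, j, k))
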