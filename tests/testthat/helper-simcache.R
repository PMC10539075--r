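# Large simulation runs shared across test files (computed once per session).
# Problem sizes: the reduced-scale preset (30 000 subjects per replicate,
# 1000 replicates) with the study's design otherwise unchanged.

.sim_store <- new.env(parent = emptyenv())

cached_null_run <- function() {
  if (is.null(.sim_store$null)) {
    cfg <- sim_config(preset = "desk", h2_d = 0, h2_i = 0)
    .sim_store$null <- run_simulation(cfg, reps = 1000, seed = 42101,
                                      n_m = c(1000, 5000),
                                      keep_replicates = TRUE)
  }
  .sim_store$null
}

# Full (nu x n_m) power grid at the calibrated effect sizes; one shared
# population/prediction model per replicate across the n_m values.
cached_power_grid <- function() {
  if (is.null(.sim_store$grid)) {
    .sim_store$grid <- lapply(c(0, 0.3, 0.5, 0.8, 1), function(nu) {
      cfg <- sim_config(preset = "desk", nu = nu, h2_d = 1e-4, h2_i = 1e-3)
      run_simulation(cfg, reps = 1000, seed = 42000L + as.integer(100 * nu),
                     n_m = c(1000, 2500, 5000), keep_replicates = TRUE)
    })
  }
  .sim_store$grid
}

# rate at one (method, n_m, alpha) cell of a wip_sim table
cell_rate <- function(sim, method, n_m, alpha = 0.05) {
  t <- sim$table
  t$rate[t$method == method & t$n_m == n_m & t$alpha == alpha]
}
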