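# Memoised expensive simulation runs shared between test files (testthat
# sources helpers once per session, so the cache persists across files).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (!exists(key, envir = .run_cache))
    assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

portugal_params <- function(eta) nondimensionalize(dimensional_parameters(eta))

corner_release_run <- function() cached_run("corner", function() {
  np <- portugal_params(0.65)
  g <- spatial_grid(4, 4, h = 0.05)
  run_spatial_multi_year(g, uniform_infestation_init(g),
                         make_release_schedule("initial-only", c(0, 0)),
                         np, n_years = 35, probes = list(c(1, 1)))
})

layout_release_run <- function(k) cached_run(paste0("layout", k), function() {
  np <- portugal_params(0.65)
  g <- spatial_grid(4, 4, h = 0.05)
  run_spatial_multi_year(g, uniform_infestation_init(g),
                         make_release_schedule("initial-only",
                                               grid_release_layout(k, 4)),
                         np, n_years = 35, probes = list(c(1, 1)),
                         store_fields = FALSE)
})

homog_run <- function(eta, n_years = 300) {
  cached_run(sprintf("homog-%g-%d", eta, n_years), function() {
    run_multi_year(params = portugal_params(eta), n_years = n_years)
  })
}
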