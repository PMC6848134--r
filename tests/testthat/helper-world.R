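# Shared fixtures: worlds are generated once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (is.null(.world_cache$tiny)) {
    .world_cache$tiny <- generate_env(world_config(nlat = 60, nlon = 120))
  }
  .world_cache$tiny
}

tiny_truth <- function() {
  if (is.null(.world_cache$tiny_truth)) {
    w <- tiny_world()
    .world_cache$tiny_truth <- generate_truth(w$env, masks = w$masks)
  }
  .world_cache$tiny_truth
}

# Independent sort-based percentile oracle (linear interpolation between
# closest order statistics), used to cross-check the package's summaries.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# A minimal hand-built environmental stack: a 3 x 4 lattice of uniform cells
# whose fields can be overridden per test.
flat_env <- function(sst_summer = 28, sst_winter = 24, sss_class = 5,
                     prod = 0.015, depth = 20, terr = "none",
                     nlat = 3, nlon = 4) {
  lat <- seq(0.5, by = 1, length.out = nlat)
  lon <- seq(10.5, by = 1, length.out = nlon)
  df <- tidyr::expand_grid(lat = lat, lon = lon)
  n <- nrow(df)
  rep_n <- function(x) rep(x, length.out = n)
  env_stack(dplyr::mutate(df,
    sst_summer = rep_n(sst_summer), sst_winter = rep_n(sst_winter),
    sss_class_summer = rep_n(sss_class), sss_class_winter = rep_n(sss_class),
    prod_summer = rep_n(prod), prod_winter = rep_n(prod),
    bathymetry = rep_n(depth), terrigenous = rep_n(terr)))
}

# Default parameters with salinity/productivity memberships neutralized, so
# presence depends on temperature alone (weights untouched).
sst_only_params <- function() {
  params <- default_factory_params()
  for (f in names(params)) {
    params[[f]]$sss <- membership_spec("independent")
    params[[f]]$prod <- membership_spec("independent")
  }
  params
}
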