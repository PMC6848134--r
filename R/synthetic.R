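#' Configuration of the synthetic world generator
#'
#' The generator builds a deterministic, seeded planet with the large-scale
#' structure the factory model assumes, so that calibration, prediction and
#' evaluation can be exercised without any satellite download:
#'
#' * a zonal SST gradient (warm equator, freezing poles) whose seasonal
#'   amplitude is small in the tropics and peaks in the mid-latitudes, giving
#'   distinct tropical (photozoan-T) and strongly seasonal warm-temperate
#'   (photo-C) regimes; seasons are stored as local warm/cool composites, so
#'   one global field pair serves both hemispheres;
#' * two meridional continents with shelves ramping to ~250 m over a few
#'   degrees, the only cells where factories can occur;
#' * subtropical salinity maxima with equatorial and polar freshening, plus a
#'   shallow marginal hypersaline gulf (>37.5 psu, warm-season SST >30.5 degC)
#'   hosting the biochemical regime;
#' * a low-productivity background with western-margin subtropical upwelling
#'   stripes raised to the upper heterozoan optimum (0.09 per m), strong
#'   enough to push the tropical factory below its presence threshold;
#' * coastal terrigenous bands: "high" patches at river mouths, a "low"
#'   fringe along all coasts, and an "arctic" band poleward of 68 deg.
#'
#' All randomness (field noise) is controlled by `seed`; the same
#' configuration always yields bit-identical stacks.
#'
#' @param nlat,nlon Grid size; the lattice is cell-centered with square cells
#'   of `2 * lat_max / nlat` degrees.
#' @param lat_max Poleward extent (degrees).
#' @param sst_eq,sst_pole Annual-mean SST at the equator and poles (deg C).
#' @param amp_eq,amp_mid Seasonal SST amplitude at the equator and at the
#'   mid-latitude peak (deg C).
#' @param amp_peak_lat,amp_width Location and width (deg latitude) of the
#'   amplitude peak.
#' @param prod_background,prod_lat_slope Background phytoplankton absorption
#'   (per m) and its poleward increase.
#' @param upwelling_prod,upwelling_lats,upwelling_width Productivity of the
#'   western-margin upwelling stripes, their latitude band, and their width
#'   in degrees longitude.
#' @param continents List of `c(lon_frac_west, lon_frac_east)` pairs, as
#'   fractions of the longitude span in (-0.5, 0.5); continents span
#'   latitudes up to `continent_lat_max`.
#' @param continent_lat_max Poleward extent of land (degrees).
#' @param shelf_width Width of the shelf depth ramp (degrees).
#' @param gulf `NULL`, or a list with `lon_frac` (two fractions), `lat` (two
#'   latitudes), `sss` (psu), `sst_boost` (deg C added to the warm season)
#'   and `depth` (m) describing the hypersaline marginal gulf.
#' @param high_terr_patches List of `c(lon_frac_west, lon_frac_east,
#'   lat_south, lat_north)` river-mouth rectangles mapped as "high"
#'   terrigenous.
#' @param low_fringe_deg Width of the coastal "low" terrigenous fringe
#'   (degrees).
#' @param arctic_lat Latitude poleward of which shelves are "arctic".
#' @param noise Named list of field noise standard deviations: `sst` (deg C,
#'   on the annual mean), `amp` (deg C, on the seasonal amplitude), `sss`
#'   (psu), `prod` (per m).
#' @param seed Integer seed fixing all randomness.
#' @return A `world_config` list.
#' @seealso [generate_env()], [calibration_world_config()]
#' @export
world_config <- function(nlat = 120, nlon = 240, lat_max = 75,
                         sst_eq = 27.5, sst_pole = -2,
                         amp_eq = 1.5, amp_mid = 8,
                         amp_peak_lat = 42, amp_width = 12,
                         prod_background = 0.018, prod_lat_slope = 0.01,
                         upwelling_prod = 0.09,
                         upwelling_lats = c(24, 31), upwelling_width = 3,
                         continents = list(c(-0.40, -0.25), c(0.05, 0.20)),
                         continent_lat_max = 70,
                         shelf_width = 8,
                         gulf = list(lon_frac = c(0.20, 0.235),
                                     lat = c(22, 30), sss = 38.5,
                                     sst_boost = 7.5, depth = 25),
                         high_terr_patches = list(c(-0.25, -0.21, -5, 8),
                                                  c(0.20, 0.24, 8, 20)),
                         low_fringe_deg = 2,
                         arctic_lat = 68,
                         noise = list(sst = 0.3, amp = 0.15, sss = 0.15,
                                      prod = 0.002),
                         seed = 1851L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nlat >= 8, cfg$nlon >= 8, cfg$lat_max > 0,
            cfg$sst_eq <= 36, cfg$sst_pole >= -2,
            cfg$prod_background >= 0, cfg$upwelling_prod >= 0)
  structure(cfg, class = "world_config")
}

#' Study conditions for calibration-recovery experiments
#'
#' A [world_config()] preset designed so an observed footprint samples the
#' full response of the membership function being recovered: the equatorial
#' annual mean is raised to 32.5 deg C so the meridional SST range crosses
#' both 0.5-crossings of the tropical SST membership; the seasonal amplitude
#' is a gentle, uniform 1 deg C (the upper threshold is a warm-season
#' percentile, so large amplitudes would leak into the recovered mid-point);
#' the hypersaline gulf is disabled so no anomalous warm patch distorts the
#' footprint; and the grid is refined so footprints exceed 2000 shelf cells.
#'
#' @param nlat,nlon Grid size.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [world_config()].
#' @return A `world_config`.
#' @export
calibration_world_config <- function(nlat = 240, nlon = 480, seed = 1851L,
                                     ...) {
  world_config(nlat = nlat, nlon = nlon, sst_eq = 32.5,
               amp_eq = 1, amp_mid = 1, gulf = NULL,
               noise = list(sst = 0.3, amp = 0, sss = 0.15, prod = 0.002),
               seed = seed, ...)
}

#' Single-parameter truth variant for calibration recovery
#'
#' A factory parameterization whose presence footprint is exactly the 0.5
#' superlevel set of one SST membership (full weight on SST, threshold 0.5),
#' used as the generating truth in parameter-recovery experiments. The low
#' terrigenous fringe is tolerated so coastal shelf cells stay in the
#' footprint.
#'
#' @param midpoint,spread Generating Gaussian parameters.
#' @return A named list with one [factory_params()].
#' @export
calibration_truth_params <- function(midpoint = 25.7, spread = 0.03) {
  list(photozoan_T = factory_params(
    "photozoan_T",
    sst = membership_spec("gaussian", midpoint, spread),
    sss = membership_spec("independent"),
    prod = membership_spec("independent"),
    weights = c(z = 0, sst = 1, sss = 0, prod = 0),
    threshold = 0.5, depth_max = 100,
    tolerates_low_terrigenous = TRUE
  ))
}

#' Generate a synthetic environmental stack and its masks
#'
#' Deterministically builds the [env_stack()] described by a
#' [world_config()], plus the eligibility masks for `params`.
#'
#' @param config A [world_config()].
#' @param params Factory parameter list used to build the masks.
#' @return A list with elements `env` ([env_stack()]) and `masks`
#'   ([build_masks()] output).
#' @examples
#' world <- generate_env(world_config(nlat = 24, nlon = 48))
#' world$env
#' @export
generate_env <- function(config = world_config(),
                         params = default_factory_params()) {
  stopifnot(inherits(config, "world_config"))
  res <- 2 * config$lat_max / config$nlat
  lat <- seq(-config$lat_max + res / 2, config$lat_max - res / 2,
             length.out = config$nlat)
  lon_half <- res * config$nlon / 2
  lon <- seq(-lon_half + res / 2, lon_half - res / 2,
             length.out = config$nlon)
  df <- tibble::tibble(lat = rep(lat, times = config$nlon),
                       lon = rep(lon, each = config$nlat))
  df <- dplyr::arrange(df, .data$lat, .data$lon)
  n <- nrow(df)
  span <- 2 * lon_half

  # distance (degrees) to the nearest continent rectangle
  rect_dist <- function(lon_pt, lat_pt, lon1, lon2, lat_abs_max) {
    dx <- pmax(lon1 - lon_pt, lon_pt - lon2, 0)
    dy <- pmax(abs(lat_pt) - lat_abs_max, 0)
    sqrt(dx^2 + dy^2)
  }
  d_land <- rep(Inf, n)
  for (ct in config$continents) {
    d_land <- pmin(d_land, rect_dist(df$lon, df$lat, ct[1] * span,
                                     ct[2] * span,
                                     config$continent_lat_max))
  }
  land <- d_land == 0

  # shelf depth ramp; deep ocean beyond
  sw <- config$shelf_width
  depth <- ifelse(d_land <= sw, 5 + 245 * (d_land / sw)^1.7, 4000)
  depth[land] <- -500

  in_gulf <- rep(FALSE, n)
  if (!is.null(config$gulf)) {
    g <- config$gulf
    in_gulf <- !land & df$lon >= g$lon_frac[1] * span &
      df$lon <= g$lon_frac[2] * span &
      df$lat >= g$lat[1] & df$lat <= g$lat[2]
    depth[in_gulf] <- g$depth
  }

  withr::with_seed(config$seed, {
    # SST: zonal mean + mid-latitude-peaked seasonal amplitude
    sst_mean <- config$sst_pole +
      (config$sst_eq - config$sst_pole) *
        cos(df$lat * pi / (2 * config$lat_max)) +
      stats::rnorm(n, 0, config$noise$sst)
    amp <- config$amp_eq +
      (config$amp_mid - config$amp_eq) *
        exp(-((abs(df$lat) - config$amp_peak_lat) / config$amp_width)^2)
    if (config$noise$amp > 0) {
      amp <- pmax(amp + stats::rnorm(n, 0, config$noise$amp), 0.05)
    }
    sst_summer <- sst_mean + amp
    sst_winter <- sst_mean - amp
    if (any(in_gulf)) {
      sst_summer[in_gulf] <- sst_summer[in_gulf] + config$gulf$sst_boost
    }
    sst_summer <- pmin(pmax(sst_summer, -2), 36)
    sst_winter <- pmin(pmax(sst_winter, -2), sst_summer)

    # SSS: subtropical maxima, equatorial and polar freshening
    sss_base <- 35 + 1.2 * exp(-((abs(df$lat) - 25) / 15)^2) -
      1.5 * exp(-(df$lat / 10)^2) -
      3 * pmax(0, (abs(df$lat) - 50) / 25)
    sss_summer <- sss_base + stats::rnorm(n, 0, config$noise$sss)
    sss_winter <- sss_base + stats::rnorm(n, 0, config$noise$sss)
    if (any(in_gulf)) {
      sss_summer[in_gulf] <- config$gulf$sss
      sss_winter[in_gulf] <- config$gulf$sss
    }
    sss_summer <- pmin(pmax(sss_summer, 29), 42)
    sss_winter <- pmin(pmax(sss_winter, 29), 42)

    # productivity: low background, poleward increase, upwelling stripes
    prod_base <- config$prod_background +
      config$prod_lat_slope * abs(df$lat) / config$lat_max
    upwelling <- rep(FALSE, n)
    for (ct in config$continents) {
      west_edge <- ct[1] * span
      upwelling <- upwelling | (!land &
        df$lon >= west_edge - config$upwelling_width - sw / 2 &
        df$lon < west_edge &
        abs(df$lat) >= config$upwelling_lats[1] &
        abs(df$lat) <= config$upwelling_lats[2])
    }
    prod_base[upwelling] <- config$upwelling_prod
    prod_summer <- pmax(prod_base + stats::rnorm(n, 0, config$noise$prod),
                        0.001)
    prod_winter <- pmax(prod_base + stats::rnorm(n, 0, config$noise$prod),
                        0.001)
  })

  # terrigenous categories
  terr <- rep("none", n)
  fringe <- !land & d_land <= config$low_fringe_deg
  terr[fringe] <- "low"
  for (p in config$high_terr_patches) {
    hit <- !land & df$lon >= p[1] * span & df$lon <= p[2] * span &
      df$lat >= p[3] & df$lat <= p[4] & depth <= 250
    terr[hit] <- "high"
  }
  arctic <- !land & abs(df$lat) >= config$arctic_lat & depth <= 250
  terr[arctic] <- "arctic"
  terr[in_gulf] <- "none"
  terr[land] <- NA_character_

  df$sst_summer <- ifelse(land, NA_real_, sst_summer)
  df$sst_winter <- ifelse(land, NA_real_, sst_winter)
  df$sss_class_summer <- ifelse(land, NA_integer_,
                                suppressMessages(
                                  reclassify_salinity(sss_summer)))
  df$sss_class_winter <- ifelse(land, NA_integer_,
                                suppressMessages(
                                  reclassify_salinity(sss_winter)))
  df$prod_summer <- ifelse(land, NA_real_, prod_summer)
  df$prod_winter <- ifelse(land, NA_real_, prod_winter)
  df$bathymetry <- depth
  df$terrigenous <- terr

  env <- env_stack(df)
  list(env = env, masks = build_masks(env, params))
}

#' Generate the synthetic "observed" factory map
#'
#' Applies the factory model under a designated truth parameterization; the
#' result serves as the synthetic observation map for calibration and
#' evaluation round trips.
#'
#' @param env An [env_stack()].
#' @param params Truth parameterization (defaults to the shipped one).
#' @param masks Optional masks.
#' @return A factory map tibble.
#' @export
generate_truth <- function(env, params = default_factory_params(),
                           masks = NULL) {
  predict_factories(env, params, masks)$map
}

#' Perturb a factory map or an environmental stack
#'
#' `perturb_map()` flips a random fraction of the assigned (non-`"none"`,
#' non-masked) cells to `"none"`; `perturb_env()` adds seeded Gaussian noise
#' to the continuous fields (the same draw is applied to both seasons of a
#' field, preserving the warm/cool ordering), truncated to physical ranges.
#'
#' @param map A factory map tibble.
#' @param flip_fraction Fraction in \[0, 1\] of assigned cells to flip.
#' @param seed Integer seed.
#' @return The same type as the input.
#' @export
perturb_map <- function(map, flip_fraction, seed = 1L) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  if (flip_fraction == 0) return(map)
  idx <- which(!is.na(map$factory) & map$factory != "none")
  k <- round(flip_fraction * length(idx))
  withr::with_seed(seed, {
    flip <- sample(idx, k)
  })
  map$factory[flip] <- "none"
  map
}

#' @rdname perturb_map
#' @param env An [env_stack()].
#' @param noise_sd Named list of noise standard deviations: any of `sst`
#'   (deg C), `prod` (per m), `bathymetry` (m).
#' @export
perturb_env <- function(env, noise_sd = list(), seed = 1L) {
  stopifnot(is_env_stack(env))
  if (length(noise_sd) == 0 || all(unlist(noise_sd) == 0)) return(env)
  n <- nrow(env)
  out <- env
  withr::with_seed(seed, {
    if (!is.null(noise_sd$sst) && noise_sd$sst > 0) {
      e <- stats::rnorm(n, 0, noise_sd$sst)
      out$sst_summer <- pmin(pmax(env$sst_summer + e, -2), 36)
      out$sst_winter <- pmin(pmax(env$sst_winter + e, -2), out$sst_summer)
    }
    if (!is.null(noise_sd$prod) && noise_sd$prod > 0) {
      e <- stats::rnorm(n, 0, noise_sd$prod)
      out$prod_summer <- pmax(env$prod_summer + e, 0)
      out$prod_winter <- pmax(env$prod_winter + e, 0)
    }
    if (!is.null(noise_sd$bathymetry) && noise_sd$bathymetry > 0) {
      e <- stats::rnorm(n, 0, noise_sd$bathymetry)
      out$bathymetry <- env$bathymetry + e
    }
  })
  env_stack(out)
}
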