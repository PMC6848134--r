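test_that("salinity reclassification matches the eight printed bins", {
  expect_identical(reclassify_salinity(36.0), 6L)
  expect_identical(reclassify_salinity(37.6), 8L)
  expect_identical(reclassify_salinity(37.5), 8L)   # open top class
  expect_identical(suppressMessages(reclassify_salinity(29.0)), 1L)
  expect_identical(reclassify_salinity(c(30, 31.5, 33, 34, 35, 35.5, 36.5)),
                   c(1L, 2L, 3L, 4L, 5L, 6L, 7L))
  expect_true(is.na(reclassify_salinity(NaN)))
  expect_message(reclassify_salinity(28), "clamped")
})

test_that("salinity reclassification is monotone and surjective on 29-41", {
  psu <- seq(29, 41, by = 0.01)
  cls <- suppressMessages(reclassify_salinity(psu))
  expect_true(all(diff(cls) >= 0))
  expect_setequal(unique(cls), 1:8)
})

test_that("grids round-trip through ASCII raster and CSV", {
  g <- tidyr::expand_grid(lat = seq(-1, 1, by = 0.5),
                          lon = seq(100, 102, by = 0.5))
  g$value <- seq_len(nrow(g)) * 1.7
  g$value[7] <- NA
  for (ext in c(".asc", ".csv")) {
    f <- tempfile(fileext = ext)
    write_grid(g, f)
    back <- read_grid(f)
    expect_equal(back$value, g$value, tolerance = 1e-12)
    expect_equal(back$lat, g$lat)
    expect_equal(back$lon, g$lon)
    unlink(f)
  }
})

test_that("ASCII rasters preserve one missing cell and report georeferencing
           errors", {
  g <- tidyr::expand_grid(lat = 1:3 - 0.5, lon = 1:3 - 0.5)
  g$value <- as.numeric(1:9)
  g$value[5] <- NA
  f <- tempfile(fileext = ".asc")
  write_grid(g, f)
  back <- read_grid(f)
  expect_identical(sum(is.na(back$value)), 1L)
  # header stripped of georeferencing -> explicit error naming the file
  lines <- readLines(f)
  f2 <- tempfile(fileext = ".asc")
  writeLines(lines[-(3:5)], f2)
  expect_error(read_grid(f2), "georeferencing")
  expect_error(read_grid(tempfile(fileext = ".asc")), "does not exist")
  unlink(c(f, f2))
})

test_that("factory maps round-trip with integer codes and a sidecar table", {
  m <- tidyr::expand_grid(lat = 1:2 - 0.5, lon = 1:3 - 0.5)
  m$factory <- c("none", "biochemical", "photozoan_T", "photo_C",
                 "heterozoan_C", NA)
  f <- tempfile(fileext = ".asc")
  write_factory_map(as_factory_map(m), f)
  expect_true(file.exists(paste0(f, ".json")))
  codes <- jsonlite::read_json(paste0(f, ".json"))$codes
  expect_identical(codes$photo_C, 3L)
  back <- read_factory_map(f)
  expect_identical(back$factory, m$factory)
  unlink(c(f, paste0(f, ".json")))
})

test_that("align_stack is a no-op on identical lattices and exact on ramps", {
  lat <- seq(-4.5, 4.5, by = 1)
  lon <- seq(0.5, 19.5, by = 1)
  ramp <- tidyr::expand_grid(lat = lat, lon = lon)
  ramp$value <- 2 * ramp$lon + 3   # linear in lon
  const <- ramp
  const$value <- 7

  same <- align_stack(list(sst_summer = ramp, sst_winter = ramp,
                           prod_summer = const, prod_winter = const,
                           bathymetry = const,
                           sss_summer = dplyr::mutate(const, value = 35)),
                      target_resolution = 1)
  expect_equal(same$sst_summer, ramp$value)

  # 2x coarsening of a linear ramp: bilinear interpolation is exact
  coarse <- align_stack(list(sst_summer = ramp, sst_winter = ramp,
                             prod_summer = const, prod_winter = const,
                             bathymetry = const,
                             sss_summer = dplyr::mutate(const, value = 35)),
                        target_resolution = 2)
  expect_equal(coarse$sst_summer, 2 * coarse$lon + 3, tolerance = 1e-9)
  expect_true(all(coarse$prod_summer == 7))
  expect_error(align_stack(list(banana = ramp), 1), "unknown field")
})

test_that("align_stack is idempotent at a fixed resolution", {
  lat <- seq(-9.5, 9.5, by = 1)
  lon <- seq(0.5, 29.5, by = 1)
  g <- tidyr::expand_grid(lat = lat, lon = lon)
  set.seed(11)
  g$value <- rnorm(nrow(g))
  mk <- function(v) dplyr::mutate(g, value = v)
  grids <- list(sst_summer = mk(g$value + 10), sst_winter = mk(g$value),
                prod_summer = mk(0.02), prod_winter = mk(0.02),
                bathymetry = mk(50), sss_summer = mk(35))
  once <- align_stack(grids, target_resolution = 2)
  again <- align_stack(list(
    sst_summer = dplyr::select(once, lat, lon, value = "sst_summer"),
    sst_winter = dplyr::select(once, lat, lon, value = "sst_winter"),
    prod_summer = dplyr::select(once, lat, lon, value = "prod_summer"),
    prod_winter = dplyr::select(once, lat, lon, value = "prod_winter"),
    bathymetry = dplyr::select(once, lat, lon, value = "bathymetry"),
    sss_class_summer = dplyr::select(once, lat, lon,
                                     value = "sss_class_summer")
  ), target_resolution = 2)
  expect_equal(again$sst_summer, once$sst_summer, tolerance = 1e-9)
  expect_equal(again$sss_class_summer, once$sss_class_summer)
})

test_that("environmental stacks validate their invariants", {
  expect_error(env_stack(tibble::tibble(lat = 1, lon = 1)), "missing columns")
  bad <- flat_env()
  bad$sst_winter <- bad$sst_summer + 2
  expect_error(env_stack(bad), "sst_summer < sst_winter")
  bad2 <- flat_env()
  bad2$prod_summer <- -0.01
  expect_error(env_stack(bad2), "negative productivity")
  bad3 <- flat_env()
  bad3$terrigenous <- "mud"
  expect_error(env_stack(bad3), "terrigenous")
  f <- tempfile(fileext = ".csv")
  write_env_stack(flat_env(), f)
  expect_equal(read_env_stack(f)$sst_summer, flat_env()$sst_summer)
  unlink(c(f, paste0(f, ".json")))
})

test_that("eligibility masks implement depth and terrigenous rules", {
  env <- flat_env(depth = c(50, 150, 50, 300, -500, 50),
                  terr = c("none", "none", "low", "none", "none", "high"),
                  nlat = 2, nlon = 3)
  masks <- build_masks(env)
  elig <- function(f) masks[[paste0("eligible_", f)]]
  # depth 50, no terrigenous: all four factories
  expect_true(all(purrr::map_lgl(names(factory_codes())[-1],
                                 ~elig(.x)[1])))
  # depth 150: only the 0-200 m factories
  expect_false(elig("biochemical")[2] || elig("photozoan_T")[2])
  expect_true(elig("photo_C")[2] && elig("heterozoan_C")[2])
  # low terrigenous: heterozoan-C only
  expect_false(elig("biochemical")[3] || elig("photozoan_T")[3] ||
                 elig("photo_C")[3])
  expect_true(elig("heterozoan_C")[3])
  # below 200 m, land, high terrigenous: nobody
  for (i in 4:6) {
    expect_false(any(purrr::map_lgl(names(factory_codes())[-1],
                                    ~elig(.x)[i])))
  }
  expect_true(masks$shelf_100[1] && !masks$shelf_100[2] &&
                masks$shelf_200[2])
})

test_that("eligibility is monotone in terrigenous pressure and depth", {
  env_hi <- flat_env(depth = 80, terr = "low")
  env_lo <- flat_env(depth = 80, terr = "none")
  env_shallow <- flat_env(depth = 30, terr = "none")
  m_hi <- build_masks(env_hi)
  m_lo <- build_masks(env_lo)
  m_sh <- build_masks(env_shallow)
  for (f in names(factory_codes())[-1]) {
    col <- paste0("eligible_", f)
    expect_true(all(m_lo[[col]] >= m_hi[[col]]))
    expect_true(all(m_sh[[col]] >= m_lo[[col]]))
  }
})
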